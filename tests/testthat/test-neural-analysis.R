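# Spike-count pipeline: windows, latency, inclusion, statistics, mean
# matching.

test_that("spike counting uses the half-open latency-shifted window", {
  tab <- trial_table(data.frame(neuron_id = "n1", condition_id = "c1",
                                trial = 1:2,
                                spike_times = I(list(c(49, 51), numeric(0))),
                                duration_ms = 200, epoch_start_ms = -50,
                                epoch_end_ms = 300))
  expect_identical(count_spikes(tab, 50), c(1L, 0L))
  # spike exactly at the window end is excluded
  tab$spike_times[[1]] <- c(50, 249.999, 250)
  expect_identical(count_spikes(tab, 50)[1], 2L)
  expect_error(count_spikes(tab, 150), "exceeds")
})

test_that("counts scale with rate for homogeneous synthetic trains", {
  cond <- data.frame(condition_id = "c1", evoked_rate = 30, gain_cv = 0)
  rec <- generate_recording(recording_spec(conditions = cond, n_trials = 500,
                                           latency_ms = 60, seed = 2))
  cnt <- count_spikes(rec$table, 60)
  expect_equal(mean(cnt), 30 * 0.2, tolerance = 0.1)
})

test_that("baseline statistics cover the [-20, 30) ms window", {
  tab <- table_from_counts(list(c1 = c(2, 2)), baseline_n = 0)
  b <- baseline_stats(tab)
  expect_equal(b$baseline_mean, 0)
  expect_equal(b$baseline_sd, 0)
  tab2 <- table_from_counts(list(c1 = c(2, 2)), baseline_n = 1)
  b2 <- baseline_stats(tab2)
  expect_equal(b2$baseline_mean, 1)
  expect_equal(b2$baseline_sd, 0)
  tab$epoch_start_ms <- 0
  expect_error(baseline_stats(tab), "baseline")
})

test_that("latency estimation finds the programmed rate step", {
  cond <- data.frame(condition_id = "c1", stim_id = "s1",
                     evoked_rate = 30, gain_cv = 0.1)
  rec <- generate_recording(recording_spec(n_neurons = 2, conditions = cond,
                                           n_trials = 150, baseline_rate = 5,
                                           latency_ms = 60, seed = 3))
  lat <- estimate_latency(rec$table)
  expect_true(all(lat$responsive))
  expect_true(all(abs(lat$latency_ms - 60) <= 10))
  # stronger steps are detected no later (monotone detection)
  cond_hi <- transform(cond, evoked_rate = 80)
  rec_hi <- generate_recording(recording_spec(n_neurons = 2, conditions = cond_hi,
                                              n_trials = 150, baseline_rate = 5,
                                              latency_ms = 60, seed = 3))
  lat_hi <- estimate_latency(rec_hi$table)
  expect_true(all(lat_hi$latency_ms <= lat$latency_ms + 2))
})

test_that("a flat PSTH yields the non-responsive flag", {
  cond <- data.frame(condition_id = "c1", evoked_rate = 5, gain_cv = 0)
  rec <- generate_recording(recording_spec(conditions = cond, n_trials = 100,
                                           baseline_rate = 5, latency_ms = 60,
                                           seed = 4))
  lat <- estimate_latency(rec$table)
  expect_false(lat$responsive[1])
  expect_true(is.na(lat$latency_ms[1]))
})

test_that("condition statistics match hand calculations and Poisson coverage", {
  s <- condition_stats(rep(4L, 10), seed = 1)
  expect_equal(s$mean, 4)
  expect_equal(s$ff, 0)
  expect_equal(diff(s$ff_ci), 0)
  s13 <- condition_stats(c(1L, 3L), seed = 1)
  expect_equal(s13$mean, 2)
  expect_equal(s13$variance, 2)   # unbiased (n - 1)
  expect_equal(s13$ff, 1)
  set.seed(5)
  sp <- condition_stats(rpois(3000, 6), seed = 2)
  expect_true(sp$ff_ci[1] <= 1 && 1 <= sp$ff_ci[2])
})

test_that("condition averaging uses arithmetic means of counts, geometric of FFs", {
  av <- average_over_conditions(c(10, 20), c(1, 4))
  expect_equal(av$mean, 15)
  expect_equal(av$ff, 2)
  expect_identical(average_over_conditions(5, 1.3)$ff, 1.3)
  suppressMessages(av0 <- average_over_conditions(c(10, 20), c(0, 4)))
  expect_equal(av0$ff, 4)
  expect_equal(av0$n_ff_excluded, 1L)
  set.seed(6)
  ffs <- runif(10, 0.5, 3)
  expect_lte(average_over_conditions(rep(1, 10), ffs)$ff, mean(ffs))
})

test_that("the symmetric percent FF change matches its definition", {
  # population FFs 1.22 (small) vs 1.15 (large) give a ~5.9% reduction
  expect_equal(percent_change_ff(1.22, 1.15), 5.907173, tolerance = 1e-6)
  expect_equal(percent_change_ff(1.3, 1.3), 0)
  expect_equal(percent_change_ff(2, 1), -percent_change_ff(1, 2))
  expect_error(percent_change_ff(0, 0), "undefined")
})

test_that("mean matching produces exactly matched histograms", {
  a <- data.frame(mean = c(2, 2, 2, 5, 5), ff = c(1.5, 1.4, 1.6, 1.3, 1.2))
  b <- data.frame(mean = c(2, 5, 5, 9, 9, 9, 9), ff = c(1.1, 1.0, 1.2, 0.9, 1.0, 1.1, 0.8))
  mm <- mean_match_ff(a, b, seed = 7)
  expect_equal(mm$n_matched, 3L)  # 1 from bin 2, 2 from bin 5
  expect_identical(table(floor(mm$matched_a$mean)), table(floor(mm$matched_b$mean)))
  expect_equal(sort(mm$histogram$n), c(1L, 2L))
  # identical groups are fully retained with zero FF difference
  mm2 <- mean_match_ff(a, a, seed = 8)
  expect_equal(mm2$n_matched, nrow(a))
  expect_equal(mm2$percent_change, 0)
  # disjoint supports fail loudly
  expect_error(mean_match_ff(a, data.frame(mean = 50, ff = 1)), "disjoint")
})

test_that("CI-overlap significance uses the closed-interval convention", {
  expect_true(significance_by_ci_overlap(c(1, 2), c(3, 4)))
  expect_false(significance_by_ci_overlap(c(1, 3), c(2, 4)))
  expect_false(significance_by_ci_overlap(c(1, 2), c(2, 3)))
})

test_that("inclusion rules fire as configured", {
  # neuron with average FF 2.5: counts alternating 0/10 -> FF = mean 5.26/ mean 5
  highff <- table_from_counts(list(c1 = c(rep(0L, 6), rep(12L, 6))),
                              neuron_id = "bad", baseline_n = 0)
  ok <- table_from_counts(list(c1 = rep(c(4L, 5L), 8)), neuron_id = "good",
                          baseline_n = 0)
  tab <- trial_table(rbind(highff, ok))
  inc <- apply_inclusion(tab)
  qc <- inc$qc
  expect_false(qc$ff_ok[qc$neuron_id == "bad"])
  expect_true(qc$included[qc$neuron_id == "good"])
  expect_false("bad" %in% inc$table$neuron_id)
  expect_true(any(grepl("bad", inc$log)))
  expect_true(all(!grepl("good", inc$log)))
  # size-tuning sanity: peak at 0.3 deg is excluded
  sz <- table_from_counts(list(s1 = rep(8L, 12), s2 = rep(3L, 12), s3 = rep(2L, 12)),
                          neuron_id = "edge",
                          meta = list(size_deg = list(s1 = 0.3, s2 = 1, s3 = 3)))
  inc_sz <- apply_inclusion(sz, rules = list(check_peak_size = TRUE))
  expect_false(inc_sz$qc$peak_size_ok[1])
})

test_that("trial tables round-trip through CSV", {
  cond <- data.frame(condition_id = c("a", "b"), size_deg = c(1, 3),
                     stim_id = "s", evoked_rate = c(20, 15), gain_cv = 0.2)
  rec <- generate_recording(recording_spec(conditions = cond, n_trials = 10,
                                           latency_ms = 60, seed = 9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_table(rec$table, path)
  back <- read_trial_table(path)
  expect_identical(count_spikes(back, 60), count_spikes(rec$table, 60))
  expect_equal(back$size_deg, rec$table$size_deg)
})
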