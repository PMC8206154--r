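# Spike-count readout and the simulated experiments.

fake_posterior <- function(g_plus, g_minus) {
  structure(list(g_samples = cbind(g_plus, g_minus),
                 n_samples = length(g_plus)),
            class = "gsm_posterior")
}

test_that("the modulus readout is the scaled quadrature energy", {
  expect_equal(spike_transform(0, 0, c = 3), 0)
  expect_equal(spike_transform(3, 4, c = 2), 10)
  expect_equal(spike_transform(c(3, -3), c(4, 4), c = 2), c(10, 10))
  expect_equal(spike_transform(2, c = 5, variant = "expansive"), 20)
  expect_equal(spike_transform(-2, c = 5, variant = "expansive"), 0)
  expect_identical(spike_transform(1.1, 0.3, c = 1, round = TRUE),
                   round(sqrt(1.1^2 + 0.3^2)))
})

test_that("response statistics: FF identity, scale algebra, degenerate cases", {
  r <- response_stats(fake_posterior(rep(3, 10), rep(4, 10)), c = 2)
  expect_equal(r$mean, 10)
  expect_equal(r$variance, 0)
  expect_equal(r$ff, 0)
  set.seed(55)
  po <- fake_posterior(rnorm(400, 3), rnorm(400))
  r1 <- response_stats(po, c = 1)
  r2 <- response_stats(po, c = 2)
  expect_equal(r2$mean, 2 * r1$mean)
  expect_equal(r2$variance, 4 * r1$variance)
  expect_equal(r2$ff, 2 * r1$ff)
  expect_equal(r1$ff * r1$mean, r1$variance, tolerance = 1e-12)
  r0 <- response_stats(fake_posterior(rep(0, 10), rep(0, 10)), c = 1)
  expect_false(r0$ff_defined)
  expect_true(is.na(r0$ff))
})

test_that("Poisson samples pushed through the readout give FF near 1", {
  set.seed(56)
  counts <- rpois(4000, 5)
  r <- response_stats(fake_posterior(counts, rep(0, 4000)), c = 1)
  expect_equal(r$ff, 1, tolerance = 0.1)
})

test_that("contrast scaling works oppositely on the analytic mean and FF", {
  C <- matrix(1)
  base <- noiseless_posterior_summary(12, C)
  for (k in c(2, 4)) {
    sk <- noiseless_posterior_summary(12 * k, C)
    expect_equal(sk$g1_mean, sqrt(k) * base$g1_mean, tolerance = 1e-12)
    expect_equal(sk$g1_ff, base$g1_ff / sqrt(k), tolerance = 1e-12)
  }
  # numeric confirmation on the exact noiseless posterior
  ex1 <- noiseless_posterior_1d(40, 1)
  ex2 <- noiseless_posterior_1d(80, 1)
  expect_equal(ex2$mean / ex1$mean, sqrt(2), tolerance = 0.02)
  expect_equal(ex1$ff / ex2$ff, sqrt(2), tolerance = 0.05)
})

test_that("the mean-variance scan reports per-image statistics and their association", {
  model <- default_model()
  imgs <- make_texture_ensemble(model$bank$spec, "pink_texture", 120, seed = 57)
  sc <- run_mean_variance_scan(model, imgs, c = 2, seed = 58)
  expect_equal(nrow(sc$table), 60)  # median selection keeps half
  expect_true(all(c("mean", "variance", "ff", "lambda") %in% names(sc$table)))
  expect_true(all(sc$table$variance >= 0))
  # variance grows with mean across images
  expect_gt(cor(sc$table$mean, sc$table$variance), 0)
  expect_true(is.finite(sc$p_value))
  # determinism
  sc2 <- run_mean_variance_scan(model, imgs, c = 2, seed = 58)
  expect_identical(sc$table, sc2$table)
})

test_that("a degenerate all-identical ensemble is flagged", {
  model <- default_model()
  img <- make_texture_ensemble(model$bank$spec, "pink_texture", 1, seed = 59)
  imgs <- array(rep(img, 4), dim = c(dim(img)[1:2], 4))
  expect_warning(sc <- run_mean_variance_scan(model, imgs, seed = 60,
                                              select_rf_above_median = FALSE),
                 "degenerate")
  expect_true(is.na(sc$pearson_r))
})

test_that("size tuning peaks at the RF size with FF falling beyond it", {
  model <- default_model()
  st <- run_size_tuning(model, make_grating(model$bank$spec, 4),
                        c = 15, seed = 61)
  expect_equal(nrow(st), 5)
  expect_true(all(st$ff * st$mean - st$variance < 1e-8 * st$variance))
  peak <- st$size_deg[which.max(st$mean)]
  expect_equal(peak, 0.90)
  beyond <- st[st$size_deg >= peak, ]
  # the exact posterior uncertainty decreases strictly with size beyond the RF
  expect_true(all(diff(beyond$g1_ff_exact) < 0))
  expect_true(all(diff(beyond$lambda) > 0))
  # and the sampled spike-count FF resolves the decrease from the RF size up
  expect_true(all(beyond$ff[-1] < beyond$ff[1]))
  expect_true(all(st$mean_lo <= st$mean & st$mean <= st$mean_hi))
  expect_true(all(st$ff_lo <= st$ff & st$ff <= st$ff_hi))
})

test_that("surround suppression of mean and FF is orientation tuned", {
  model <- default_model()
  so <- run_surround_orientation(model, seed = 62)
  ctr <- so[so$condition == "center_alone", ]
  mat <- so[so$surround_orientation %in% 90, ]
  ort <- so[so$surround_orientation %in% 180, ]
  expect_lt(mat$mean, ctr$mean)
  expect_lt(mat$ff, ctr$ff)
  expect_lt(mat$mean, ort$mean)
  expect_lt(mat$ff, ort$ff)
  expect_gt(mat$E_nu, ort$E_nu)
  # zero-contrast surround reproduces center-alone up to Monte Carlo error
  spec <- model$bank$spec
  x_c <- apply_filterbank(model$bank, make_grating(spec, 0.9))
  x_0 <- apply_filterbank(model$bank,
                          make_compound_grating(spec, 0.9, 1.1, 3.8,
                                                surround_contrast = 0))
  expect_equal(x_c, x_0, tolerance = 1e-10)
})
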