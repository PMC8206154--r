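# Spike-count analysis pipeline for trial-aligned recordings: counting
# windows, latency estimation, inclusion criteria, Fano factors, size/surround
# tuning statistics, symmetric percent changes, mean matching, bootstrap CIs
# and t tests. Applies identically to surrogate recordings from
# generate_recording() and to real trial tables with the same schema.

#' Construct / validate a trial table
#'
#' A trial table has one row per (neuron, condition, trial) with the spike
#' times of that trial in milliseconds relative to stimulus onset, plus
#' condition metadata. Required columns: `neuron_id`, `condition_id`, `trial`,
#' `spike_times` (list-column of numeric vectors), `duration_ms`,
#' `epoch_start_ms`, `epoch_end_ms`. Optional metadata: `size_deg`, `stim_id`,
#' `surround`, `rf_offset_deg`.
#'
#' @param df A data frame with the columns above.
#' @return The validated data frame, class `trial_table`.
#' @export
trial_table <- function(df) {
  req <- c("neuron_id", "condition_id", "trial", "spike_times",
           "duration_ms", "epoch_start_ms", "epoch_end_ms")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("trial table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L) stop("trial table is empty", call. = FALSE)
  if (!is.list(df$spike_times))
    stop("spike_times must be a list-column of numeric vectors", call. = FALSE)
  bad <- which(!vapply(df$spike_times, function(s) all(is.finite(s)), logical(1)))
  if (length(bad))
    stop("non-finite spike times in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  if (any(df$duration_ms <= 0)) stop("duration_ms must be positive", call. = FALSE)
  if (!inherits(df, "trial_table")) class(df) <- c("trial_table", class(df))
  df
}

#' Read / write a trial table as CSV
#'
#' Spike times are serialized as a `;`-separated string per trial, so the
#' table round-trips through plain text.
#'
#' @param path CSV file path.
#' @rdname trial_table_io
#' @export
read_trial_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"spike_times" %in% names(df))
    stop("not a trial table: no spike_times column in ", path, call. = FALSE)
  df$spike_times <- lapply(df$spike_times, function(s) {
    if (is.na(s) || !nzchar(s)) numeric(0)
    else as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  })
  trial_table(df)
}

#' @param table A [trial_table()].
#' @rdname trial_table_io
#' @export
write_trial_table <- function(table, path) {
  df <- as.data.frame(table)
  df$spike_times <- vapply(df$spike_times,
                           function(s) paste(format(s, trim = TRUE, digits = 10),
                                             collapse = ";"),
                           character(1))
  df$spike_times[df$spike_times == ""] <- ""
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

latency_for_rows <- function(table, latency_ms) {
  if (length(latency_ms) == 1L && is.null(names(latency_ms)))
    rep(unname(latency_ms), nrow(table))
  else {
    lat <- latency_ms[as.character(table$neuron_id)]
    if (anyNA(lat))
      stop("latency missing for neuron(s): ",
           paste(unique(table$neuron_id[is.na(lat)]), collapse = ", "),
           call. = FALSE)
    unname(lat)
  }
}

#' Count spikes in the stimulus-locked window
#'
#' Counts spikes in the half-open window
#' `[onset + latency, onset + latency + duration)` — half-open so that
#' adjacent windows never double-count a spike.
#'
#' @param table A [trial_table()].
#' @param latency_ms Scalar latency, or a named vector of per-neuron
#'   latencies (names = neuron ids). Default 50 ms, the fixed shift used
#'   before per-neuron latencies are available.
#' @return Integer vector of counts, one per table row.
#' @export
count_spikes <- function(table, latency_ms = 50) {
  table <- trial_table(table)
  lat <- latency_for_rows(table, latency_ms)
  hi <- lat + table$duration_ms
  if (any(lat < table$epoch_start_ms | hi > table$epoch_end_ms))
    stop("counting window exceeds the recorded epoch for some trials",
         call. = FALSE)
  vapply(seq_len(nrow(table)), function(i) {
    s <- table$spike_times[[i]]
    sum(s >= lat[i] & s < hi[i])
  }, integer(1))
}

#' Baseline activity per neuron
#'
#' Mean and SD of spike counts in the fixed 50 ms baseline window from 20 ms
#' before to 30 ms after stimulus onset, across all trials of each neuron.
#'
#' @param table A [trial_table()].
#' @return `data.frame` with `neuron_id`, `baseline_mean`, `baseline_sd`
#'   (counts per 50 ms window).
#' @export
baseline_stats <- function(table) {
  table <- trial_table(table)
  if (any(table$epoch_start_ms > -20))
    stop("epochs must include the [-20, 30) ms baseline window", call. = FALSE)
  counts <- vapply(table$spike_times,
                   function(s) sum(s >= -20 & s < 30), integer(1))
  agg <- stats::aggregate(counts, by = list(neuron_id = table$neuron_id),
                          FUN = function(v) c(mean(v), stats::sd(v)))
  data.frame(neuron_id = agg$neuron_id,
             baseline_mean = agg$x[, 1],
             baseline_sd = ifelse(is.na(agg$x[, 2]), 0, agg$x[, 2]))
}

# Smoothed PSTH (1 ms bins, spikes/s) for a set of trials.
smoothed_psth <- function(spikes, t_lo, t_hi, spline_param = 2e-6) {
  breaks <- seq(floor(t_lo), ceiling(t_hi), by = 1)
  mids <- breaks[-length(breaks)] + 0.5
  all_s <- unlist(spikes)
  cnt <- if (length(all_s))
    graphics::hist(all_s[all_s >= breaks[1] & all_s < breaks[length(breaks)]],
                   breaks = breaks, plot = FALSE)$counts
  else rep(0L, length(mids))
  rate <- cnt / (length(spikes) * 1e-3)        # spikes/s per 1 ms bin
  # roughness penalty applied on the seconds time axis
  fit <- stats::smooth.spline(mids / 1000, rate, lambda = spline_param)
  list(t_ms = mids, rate = stats::predict(fit, mids / 1000)$y)
}

#' Estimate per-neuron response latency
#'
#' The latency is the first time after stimulus onset at which the smoothed
#' peristimulus time histogram (1 ms bins, regularized by a smoothing cubic
#' spline with roughness parameter `spline_param` on the seconds time axis)
#' crosses baseline mean + 1 baseline SD. For size-tuning tables the PSTH is
#' computed at each neuron's preferred (maximal mean count) size; otherwise at
#' the smallest size presented, or over all conditions when no size metadata
#' exists. Neurons whose PSTH never crosses threshold are flagged
#' non-responsive (`NA` latency).
#'
#' @param table A [trial_table()].
#' @param spline_param Smoothing-spline roughness penalty (default 2e-6).
#' @return `data.frame` with `neuron_id`, `latency_ms`, `responsive`.
#' @export
estimate_latency <- function(table, spline_param = 2e-6) {
  table <- trial_table(table)
  bl <- baseline_stats(table)
  out <- lapply(split(seq_len(nrow(table)), table$neuron_id), function(idx) {
    sub <- table[idx, ]
    nid <- sub$neuron_id[1]
    rows <- if ("size_deg" %in% names(sub) && any(is.finite(sub$size_deg))) {
      cnt <- count_spikes(sub, 50)
      mu <- tapply(cnt, sub$size_deg, mean)
      pref <- as.numeric(names(mu)[which.max(mu)])
      sub[sub$size_deg == pref, ]
    } else sub
    ps <- smoothed_psth(rows$spike_times, rows$epoch_start_ms[1],
                        rows$epoch_end_ms[1], spline_param)
    b <- bl[bl$neuron_id == nid, ]
    thr <- (b$baseline_mean + b$baseline_sd) / 0.05   # counts/50ms -> spikes/s
    post <- ps$t_ms > 0
    cross <- which(post & ps$rate >= thr)
    data.frame(neuron_id = nid,
               latency_ms = if (length(cross)) ps$t_ms[min(cross)] else NA_real_,
               responsive = length(cross) > 0)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-condition spike-count statistics with bootstrap CIs
#'
#' Mean, unbiased variance, Fano factor, and 68% percentile bootstrap
#' confidence intervals (trial resampling) for the mean and the FF.
#'
#' @param counts Integer spike counts (>= 2 trials).
#' @param n_boot Bootstrap resamples.
#' @param seed Integer seed.
#' @return List with `mean`, `variance`, `ff`, `ff_defined`, `n_trials`,
#'   `mean_ci`, `ff_ci`.
#' @export
condition_stats <- function(counts, n_boot = 1000L, seed = NULL) {
  stopifnot(length(counts) >= 2, all(is.finite(counts)))
  m <- mean(counts)
  v <- stats::var(counts)
  seeds <- child_seeds(seed, 2L)
  list(mean = m, variance = v,
       ff = if (m > 0) v / m else NA_real_,
       ff_defined = m > 0,
       n_trials = length(counts),
       mean_ci = boot_ci68(counts, mean, n_boot, seeds[[1]]),
       ff_ci = boot_ci68(counts, ff_stat, n_boot, seeds[[2]]))
}

#' Average tuning statistics across stimulus conditions
#'
#' Combines per-condition statistics into a per-neuron curve point using the
#' arithmetic mean for spike counts and the geometric mean for Fano factors
#' (the standard choice for ratio statistics). Conditions with FF = 0 or
#' undefined FF are excluded from the geometric mean with a log message.
#'
#' @param means Per-condition mean counts.
#' @param ffs Per-condition Fano factors.
#' @return List with `mean` (arithmetic), `ff` (geometric mean),
#'   `n_ff_excluded`.
#' @export
average_over_conditions <- function(means, ffs) {
  stopifnot(length(means) == length(ffs))
  ok <- is.finite(ffs) & ffs > 0
  if (!any(ok))
    return(list(mean = mean(means), ff = NA_real_, n_ff_excluded = sum(!ok)))
  if (any(!ok))
    message(sum(!ok), " condition(s) with zero/undefined FF excluded from the geometric mean")
  list(mean = mean(means), ff = exp(mean(log(ffs[ok]))),
       n_ff_excluded = sum(!ok))
}

#' Symmetric percent change in Fano factor
#'
#' `100 * (FF_alpha - FF_beta) / ((FF_alpha + FF_beta)/2)`, with `alpha` the
#' condition nearer the RF size (or with orthogonal surround) and `beta` the
#' larger (or matched-surround) condition, so a positive value means the FF is
#' lower in the `beta` condition.
#'
#' @param ff_alpha,ff_beta Fano factors of the two conditions.
#' @return Percent change (antisymmetric in its arguments).
#' @export
percent_change_ff <- function(ff_alpha, ff_beta) {
  s <- ff_alpha + ff_beta
  if (any(s <= 0)) stop("percent change undefined: FF_alpha + FF_beta must be > 0",
                        call. = FALSE)
  100 * (ff_alpha - ff_beta) / (s / 2)
}

#' Mean-matched Fano factor comparison
#'
#' Bins the mean spike counts of the two groups (default: unit-width bins) and
#' subsamples, without replacement, `min(n_A, n_B)` cases per bin from each
#' group, so the binned mean-count histograms of the matched subsets are
#' identical by construction. FF distributions of the matched subsets are then
#' compared with a one-sided paired t test (pairing within bins, in sampled
#' order) of the null hypothesis that the A - B difference has mean <= 0.
#'
#' @param group_a,group_b Data frames with columns `mean` and `ff` (one row
#'   per neuron-condition case). Group A is the high-FF-expected group (e.g.
#'   stimuli smaller than the RF).
#' @param bin_width Histogram bin width on the mean-count axis.
#' @param seed Integer seed for the subsampling.
#' @return List with `matched_a`, `matched_b` (matched subsets, one row per
#'   case, in paired order), `n_matched`, `ff_mean_a`, `ff_mean_b`,
#'   `percent_change` (symmetric percent change of the mean FFs), `t_test`
#'   (one-sided paired), and the per-bin `histogram`.
#' @export
mean_match_ff <- function(group_a, group_b, bin_width = 1, seed = NULL) {
  stopifnot(all(c("mean", "ff") %in% names(group_a)),
            all(c("mean", "ff") %in% names(group_b)))
  bin_a <- floor(group_a$mean / bin_width)
  bin_b <- floor(group_b$mean / bin_width)
  shared <- intersect(unique(bin_a), unique(bin_b))
  if (length(shared) == 0L)
    stop("mean-count supports are disjoint: no matched cases", call. = FALSE)
  seeds <- child_seeds(seed, length(shared))
  ia <- integer(0); ib <- integer(0); hist_n <- integer(0)
  for (k in seq_along(shared)) {
    a_idx <- which(bin_a == shared[k])
    b_idx <- which(bin_b == shared[k])
    m <- min(length(a_idx), length(b_idx))
    pick <- with_seed(seeds[[k]], list(
      a = if (length(a_idx) == m) a_idx else sample(a_idx, m),
      b = if (length(b_idx) == m) b_idx else sample(b_idx, m)))
    ia <- c(ia, pick$a); ib <- c(ib, pick$b); hist_n <- c(hist_n, m)
  }
  ma <- group_a[ia, , drop = FALSE]
  mb <- group_b[ib, , drop = FALSE]
  tt <- stats::t.test(ma$ff, mb$ff, paired = TRUE, alternative = "greater")
  list(matched_a = ma, matched_b = mb, n_matched = nrow(ma),
       ff_mean_a = mean(ma$ff), ff_mean_b = mean(mb$ff),
       percent_change = percent_change_ff(mean(ma$ff), mean(mb$ff)),
       t_test = tt,
       histogram = data.frame(bin = shared, n = hist_n))
}

#' Significance by non-overlap of 68% confidence intervals
#'
#' TRUE iff the two intervals are disjoint; intervals that merely touch at an
#' endpoint are treated as overlapping (closed-interval convention).
#'
#' @param ci_a,ci_b Length-2 numeric vectors `c(lo, hi)`.
#' @export
significance_by_ci_overlap <- function(ci_a, ci_b) {
  stopifnot(length(ci_a) == 2, length(ci_b) == 2)
  ci_a <- sort(ci_a); ci_b <- sort(ci_b)
  ci_a[2] < ci_b[1] || ci_b[2] < ci_a[1]
}

#' Apply inclusion criteria to a trial table
#'
#' Configurable quality-control rules mirroring the study's inclusion
#' criteria. Always checked: responsivity (some condition drives the neuron
#' above baseline mean + 1 SD) and average FF across conditions `<= max_ff`.
#' Optional rules (enabled per experiment type): peak-size sanity for
#' size-tuning data (peak response not at `<= 0.3` deg nor `> 4` deg),
#' RF centering (metadata column `rf_offset_deg <= 0.4`), a minimum number of
#' images driving the neuron significantly, positive mean count in every
#' condition (the FF is undefined otherwise), and — per stimulus rather than
#' per neuron — minimum surround suppression of the mean count.
#'
#' @param table A [trial_table()].
#' @param rules List of rule settings: `max_ff` (default 2),
#'   `check_peak_size`, `check_rf_center`, `min_images` (0 = off),
#'   `require_nonzero_mean`, `min_surround_suppression` (fraction, NA = off;
#'   compares largest vs near-1-degree size per stimulus).
#' @param latency_ms Latency used for counting (scalar or per-neuron vector).
#' @return List with `qc` (one row per neuron: flags and `included`),
#'   `table` (rows of included neurons/conditions), `log` (character record
#'   of every rule that fired).
#' @export
apply_inclusion <- function(table,
                            rules = list(),
                            latency_ms = 50) {
  table <- trial_table(table)
  rules <- utils::modifyList(list(max_ff = 2, check_peak_size = FALSE,
                                  check_rf_center = FALSE, min_images = 0L,
                                  require_nonzero_mean = TRUE,
                                  min_surround_suppression = NA_real_),
                             rules)
  counts <- count_spikes(table, latency_ms)
  bl <- baseline_stats(table)
  log <- character(0)
  drop_rows <- rep(FALSE, nrow(table))

  # per-stimulus surround-suppression rule (size-tuning tables)
  if (is.finite(rules$min_surround_suppression) && "size_deg" %in% names(table) &&
      "stim_id" %in% names(table)) {
    for (sid in unique(table$stim_id)) {
      sel <- table$stim_id == sid
      mu <- tapply(counts[sel], table$size_deg[sel], mean)
      szs <- as.numeric(names(mu))
      near1 <- szs[which.min(abs(log(szs / 1)))]
      supp <- 1 - mu[as.character(max(szs))] / mu[as.character(near1)]
      if (!is.finite(supp) || supp < rules$min_surround_suppression) {
        drop_rows <- drop_rows | sel
        log <- c(log, sprintf("stimulus %s excluded: surround suppression %.1f%% < %.0f%%",
                              sid, 100 * supp, 100 * rules$min_surround_suppression))
      }
    }
  }

  qc <- lapply(split(seq_len(nrow(table)), table$neuron_id), function(idx) {
    idx <- idx[!drop_rows[idx]]
    if (length(idx) == 0L)
      return(NULL)
    sub <- table[idx, ]
    nid <- sub$neuron_id[1]
    cnt <- counts[idx]
    b <- bl[bl$neuron_id == nid, ]
    mu_cond <- tapply(cnt, sub$condition_id, mean)
    ff_cond <- tapply(cnt, sub$condition_id,
                      function(v) if (mean(v) > 0) stats::var(v) / mean(v) else NA_real_)
    # responsivity: scale the 50 ms baseline to the counting-window length
    thr <- (b$baseline_mean + b$baseline_sd) * sub$duration_ms[1] / 50
    responsive <- any(mu_cond > thr)
    ff_ok <- mean(ff_cond, na.rm = TRUE) <= rules$max_ff
    flags <- c(responsive = responsive, ff_ok = ff_ok)
    if (rules$check_peak_size && "size_deg" %in% names(sub)) {
      mu_sz <- tapply(cnt, sub$size_deg, mean)
      pk <- as.numeric(names(mu_sz)[which.max(mu_sz)])
      flags["peak_size_ok"] <- pk > 0.3 && pk <= 4
    }
    if (rules$check_rf_center && "rf_offset_deg" %in% names(sub))
      flags["centering_ok"] <- all(sub$rf_offset_deg <= 0.4)
    if (rules$min_images > 0L && "stim_id" %in% names(sub)) {
      mu_img <- tapply(cnt, sub$stim_id, mean)
      flags["enough_images"] <- sum(mu_img > thr) >= rules$min_images
    }
    if (rules$require_nonzero_mean)
      flags["nonzero_mean"] <- all(mu_cond > 0)
    df <- data.frame(neuron_id = nid, t(as.data.frame(flags)))
    df$included <- all(flags)
    rownames(df) <- NULL
    df
  })
  qc <- do.call(rbind, qc)
  for (i in seq_len(nrow(qc))) {
    fl <- qc[i, setdiff(names(qc), c("neuron_id", "included")), drop = FALSE]
    fired <- names(fl)[!unlist(fl)]
    if (length(fired))
      log <- c(log, sprintf("neuron %s excluded: %s",
                            qc$neuron_id[i], paste(fired, collapse = ", ")))
  }
  keep_neurons <- qc$neuron_id[qc$included]
  out <- table[!drop_rows & table$neuron_id %in% keep_neurons, ]
  list(qc = qc, table = if (nrow(out)) trial_table(out) else out, log = log)
}

#' Full size-tuning analysis of a trial table
#'
#' Runs the complete pipeline on size-tuning data: baseline and latency
#' estimation, latency-shifted counting, inclusion criteria, per-neuron
#' per-size statistics (averaged over stimuli: arithmetic mean of counts,
#' geometric mean of FFs), symmetric percent FF changes from the size nearest
#' half the RF size to the RF size and from the RF size to twice the RF size
#' (sizes chosen by minimal absolute log ratio; RF size = preferred size,
#' i.e. the peak of the mean-count curve), the associated one-sided paired
#' t test, and the mean-matched small-vs-large FF comparison.
#'
#' @param table A [trial_table()] with `size_deg` metadata.
#' @param rules Inclusion rules, see [apply_inclusion()].
#' @param n_boot Bootstrap resamples for condition CIs.
#' @param seed Integer seed.
#' @return List with `qc`, `latency`, `curves` (per neuron x size: mean, ff),
#'   `percent_changes` (per neuron: half-to-RF and RF-to-2RF), `t_half_rf`,
#'   `t_rf_2rf` (one-sided paired t tests), `mean_match`, and `log`.
#' @export
analyze_size_tuning <- function(table, rules = list(check_peak_size = TRUE),
                                n_boot = 1000L, seed = NULL) {
  table <- trial_table(table)
  if (!"size_deg" %in% names(table))
    stop("size-tuning analysis needs a size_deg column", call. = FALSE)
  lat <- estimate_latency(table)
  lat_v <- stats::setNames(lat$latency_ms, lat$neuron_id)
  lat_v[is.na(lat_v)] <- 50
  inc <- apply_inclusion(table, rules, latency_ms = lat_v)
  tab <- inc$table
  if (NROW(tab) == 0L)
    stop("no neurons pass the inclusion criteria", call. = FALSE)
  counts <- count_spikes(tab, lat_v)
  seeds <- child_seeds(seed, 2L)

  curves <- list()
  for (nid in unique(tab$neuron_id)) {
    sel <- tab$neuron_id == nid
    for (sz in sort(unique(tab$size_deg[sel]))) {
      s2 <- sel & tab$size_deg == sz
      stim <- if ("stim_id" %in% names(tab)) tab$stim_id[s2] else 1L
      mus <- tapply(counts[s2], stim, mean)
      ffs <- tapply(counts[s2], stim,
                    function(v) if (mean(v) > 0) stats::var(v) / mean(v) else NA_real_)
      av <- average_over_conditions(as.numeric(mus), as.numeric(ffs))
      curves[[length(curves) + 1L]] <-
        data.frame(neuron_id = nid, size_deg = sz, mean = av$mean, ff = av$ff)
    }
  }
  curves <- do.call(rbind, curves)

  pc <- lapply(split(curves, curves$neuron_id), function(cv) {
    cv <- cv[order(cv$size_deg), ]
    rf <- cv$size_deg[which.max(cv$mean)]
    nearest <- function(target) cv$size_deg[which.min(abs(log(cv$size_deg / target)))]
    s_half <- nearest(rf / 2); s_rf <- nearest(rf); s_2rf <- nearest(2 * rf)
    ffat <- function(s) cv$ff[cv$size_deg == s][1]
    data.frame(neuron_id = cv$neuron_id[1], rf_size = rf,
               size_half = s_half, size_2rf = s_2rf,
               ff_half = ffat(s_half), ff_rf = ffat(s_rf), ff_2rf = ffat(s_2rf),
               pct_half_rf = if (s_half < s_rf)
                 percent_change_ff(ffat(s_half), ffat(s_rf)) else NA_real_,
               pct_rf_2rf = if (s_2rf > s_rf)
                 percent_change_ff(ffat(s_rf), ffat(s_2rf)) else NA_real_)
  })
  pc <- do.call(rbind, pc)
  rownames(pc) <- NULL

  one_sided <- function(a, b) {
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) >= 2) stats::t.test(a[ok], b[ok], paired = TRUE,
                                    alternative = "greater")
    else NULL
  }
  # mean matching: pool neuron x size cases below vs above each neuron's RF size
  small <- list(); large <- list()
  for (nid in unique(curves$neuron_id)) {
    cv <- curves[curves$neuron_id == nid, ]
    rf <- pc$rf_size[pc$neuron_id == nid]
    small[[nid]] <- cv[cv$size_deg < rf, c("mean", "ff")]
    large[[nid]] <- cv[cv$size_deg > rf, c("mean", "ff")]
  }
  small <- do.call(rbind, small); large <- do.call(rbind, large)
  mm <- if (NROW(small) && NROW(large))
    tryCatch(mean_match_ff(small, large, seed = seeds[[1]]),
             error = function(e) {message(conditionMessage(e)); NULL})
  else NULL

  list(qc = inc$qc, latency = lat, curves = curves, percent_changes = pc,
       t_half_rf = one_sided(pc$ff_half, pc$ff_rf),
       t_rf_2rf = one_sided(pc$ff_rf, pc$ff_2rf),
       mean_match = mm, log = inc$log)
}

#' Two-size Fano factor comparison (small vs large stimuli)
#'
#' For tables with exactly two stimulus sizes per neuron (RF-sized versus
#' extending into the surround), computes each neuron's FF per size (geometric
#' mean over stimuli), the per-neuron significance of the FF change (two-sided
#' paired t test across stimuli of the per-stimulus FFs), the fraction of
#' significantly changing neurons whose FF is lower for the large size, and
#' the population-level two-sided paired t test of the per-neuron FFs.
#'
#' @param table A [trial_table()] with `size_deg` taking two values and
#'   `stim_id` metadata.
#' @param rules Inclusion rules.
#' @param alpha Per-neuron significance level.
#' @param seed Integer seed (latency handling only; the tests are
#'   deterministic).
#' @return List with `per_neuron` (ff_small, ff_large, p, significant),
#'   `ff_small_mean`, `ff_large_mean`, `population_t` (two-sided paired),
#'   `n_significant`, `frac_lower_large` (direction consistency among
#'   significant neurons).
#' @export
analyze_two_size_ff <- function(table, rules = list(), alpha = 0.05,
                                seed = NULL) {
  table <- trial_table(table)
  szs <- sort(unique(table$size_deg))
  if (length(szs) != 2L)
    stop("two-size analysis needs exactly two stimulus sizes", call. = FALSE)
  lat <- estimate_latency(table)
  lat_v <- stats::setNames(lat$latency_ms, lat$neuron_id)
  lat_v[is.na(lat_v)] <- 50
  inc <- apply_inclusion(table, rules, latency_ms = lat_v)
  tab <- inc$table
  counts <- count_spikes(tab, lat_v)
  per <- lapply(split(seq_len(nrow(tab)), tab$neuron_id), function(idx) {
    sub <- tab[idx, ]; cnt <- counts[idx]
    stim <- if ("stim_id" %in% names(sub)) sub$stim_id else 1L
    ff_tab <- tapply(seq_along(cnt), list(stim, sub$size_deg), function(j) {
      m <- mean(cnt[j]); if (m > 0) stats::var(cnt[j]) / m else NA_real_
    })
    if (is.null(dim(ff_tab)) || ncol(ff_tab) < 2) return(NULL)
    f_small <- ff_tab[, as.character(szs[1])]
    f_large <- ff_tab[, as.character(szs[2])]
    ok <- is.finite(f_small) & is.finite(f_large)
    p <- if (sum(ok) >= 2)
      stats::t.test(f_small[ok], f_large[ok], paired = TRUE)$p.value
    else NA_real_
    data.frame(neuron_id = sub$neuron_id[1],
               ff_small = exp(mean(log(f_small[ok & f_small > 0]))),
               ff_large = exp(mean(log(f_large[ok & f_large > 0]))),
               p = p)
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  per$significant <- is.finite(per$p) & per$p < alpha
  sig <- per[per$significant, ]
  pop <- stats::t.test(per$ff_small, per$ff_large, paired = TRUE)
  list(per_neuron = per,
       ff_small_mean = mean(per$ff_small, na.rm = TRUE),
       ff_large_mean = mean(per$ff_large, na.rm = TRUE),
       population_t = pop,
       n_significant = nrow(sig),
       frac_lower_large = if (nrow(sig)) mean(sig$ff_large < sig$ff_small)
                          else NA_real_,
       qc = inc$qc, log = inc$log)
}
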