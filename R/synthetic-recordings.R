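# Surrogate trial-aligned recordings with known ground truth.
#
# Each trial is a gain-modulated (doubly stochastic) Poisson train: a
# trial-specific multiplicative gain with mean 1 and coefficient of variation
# gain_cv scales the evoked rate, so the spike count in the evoked window has
#   FF = 1 + mean_count * gain_cv^2
# by the law of total variance. This is the minimal structure matching what
# the analysis pipeline assumes: Poisson baseline, latency-delayed evoked
# response, and super-Poisson across-trial variability whose strength is
# programmable per condition.

#' Specify a surrogate recording
#'
#' @param n_neurons Number of neurons.
#' @param conditions Data frame with one row per condition: `condition_id`
#'   plus metadata (`size_deg`, `stim_id`, `surround`, ...), and per-condition
#'   `evoked_rate` (spikes/s) and `gain_cv` (coefficient of variation of the
#'   trial gain, >= 0).
#' @param n_trials Trials per condition.
#' @param baseline_rate Baseline rate, spikes/s.
#' @param latency_ms Per-neuron latency (scalar or length `n_neurons`).
#' @param duration_ms Stimulus duration (counting-window length).
#' @param epoch_ms Recorded epoch `c(start, end)` relative to onset.
#' @param seed Integer seed.
#' @return Object of class `recording_spec`.
#' @export
recording_spec <- function(n_neurons = 1L, conditions,
                           n_trials = 100L, baseline_rate = 5,
                           latency_ms = 60, duration_ms = 200,
                           epoch_ms = c(-50, 350), seed = NULL) {
  stopifnot(is.data.frame(conditions),
            all(c("condition_id", "evoked_rate", "gain_cv") %in% names(conditions)),
            all(conditions$evoked_rate >= 0), all(conditions$gain_cv >= 0),
            n_trials >= 2, baseline_rate >= 0, duration_ms > 0,
            epoch_ms[1] <= -20, epoch_ms[2] >= max(latency_ms) + duration_ms)
  if (length(latency_ms) == 1L) latency_ms <- rep(latency_ms, n_neurons)
  stopifnot(length(latency_ms) == n_neurons)
  structure(list(n_neurons = as.integer(n_neurons), conditions = conditions,
                 n_trials = as.integer(n_trials), baseline_rate = baseline_rate,
                 latency_ms = latency_ms, duration_ms = duration_ms,
                 epoch_ms = epoch_ms, seed = seed),
            class = "recording_spec")
}

poisson_train <- function(rate_hz, t0, t1) {
  if (rate_hz <= 0 || t1 <= t0) return(numeric(0))
  n <- stats::rpois(1L, rate_hz * (t1 - t0) / 1000)
  sort(stats::runif(n, t0, t1))
}

#' Generate a surrogate recording
#'
#' Emits a [trial_table()] plus the analytic ground truth per condition:
#' expected count `evoked_rate * duration`, and
#' `FF = 1 + mean_count * gain_cv^2`.
#'
#' @param spec A [recording_spec()].
#' @return List with `table` (a [trial_table()]) and `ground_truth`
#'   (`data.frame`: condition_id, mean_count, ff).
#' @export
generate_recording <- function(spec) {
  stopifnot(inherits(spec, "recording_spec"))
  cond <- spec$conditions
  rows <- with_seed(spec$seed, {
    out <- vector("list", spec$n_neurons * nrow(cond))
    k <- 0L
    for (ni in seq_len(spec$n_neurons)) {
      lat <- spec$latency_ms[ni]
      for (ci in seq_len(nrow(cond))) {
        cv <- cond$gain_cv[ci]
        trains <- lapply(seq_len(spec$n_trials), function(tr) {
          gain <- if (cv > 0) stats::rgamma(1L, shape = 1 / cv^2, scale = cv^2) else 1
          c(poisson_train(spec$baseline_rate, spec$epoch_ms[1], lat),
            poisson_train(gain * cond$evoked_rate[ci], lat, spec$epoch_ms[2]))
        })
        k <- k + 1L
        out[[k]] <- data.frame(neuron_id = sprintf("n%02d", ni),
                               condition_id = cond$condition_id[ci],
                               trial = seq_len(spec$n_trials),
                               spike_times = I(trains),
                               duration_ms = spec$duration_ms,
                               epoch_start_ms = spec$epoch_ms[1],
                               epoch_end_ms = spec$epoch_ms[2])
      }
    }
    out
  })
  tab <- do.call(rbind, rows)
  meta_cols <- setdiff(names(cond), c("evoked_rate", "gain_cv"))
  tab <- merge(tab, cond[, meta_cols, drop = FALSE], by = "condition_id",
               sort = FALSE)
  mean_count <- cond$evoked_rate * spec$duration_ms / 1000
  list(table = trial_table(tab),
       ground_truth = data.frame(condition_id = cond$condition_id,
                                 mean_count = mean_count,
                                 ff = 1 + mean_count * cond$gain_cv^2))
}

#' Build a size-tuning fixture with programmed Fano factors
#'
#' Inverts the generator's identity `FF = 1 + mean * gain_cv^2` to find the
#' per-size gain CV that realizes the requested FF targets; FF targets below 1
#' are outside this (super-Poisson) generator family and raise an error.
#'
#' @param sizes Stimulus diameters, degrees.
#' @param ff_targets Target FF per size (>= 1).
#' @param mean_targets Target mean count per size.
#' @param ... Passed to [recording_spec()] (`n_neurons`, `n_trials`, `seed`,
#'   ...).
#' @param duration_ms Counting-window length.
#' @return A [recording_spec()] whose conditions carry `size_deg` metadata.
#' @export
make_size_tuning_fixture <- function(sizes, ff_targets, mean_targets,
                                     duration_ms = 200, ...) {
  stopifnot(length(sizes) == length(ff_targets),
            length(sizes) == length(mean_targets), all(mean_targets > 0))
  if (any(ff_targets < 1))
    stop("FF targets below 1 cannot be expressed by the gain-modulated ",
         "Poisson family (sub-Poisson counts need a different count model)",
         call. = FALSE)
  gain_cv <- sqrt((ff_targets - 1) / mean_targets)
  cond <- data.frame(condition_id = sprintf("size_%g", sizes),
                     size_deg = sizes, stim_id = "img1",
                     evoked_rate = mean_targets / (duration_ms / 1000),
                     gain_cv = gain_cv)
  recording_spec(conditions = cond, duration_ms = duration_ms, ...)
}

#' Write a generated recording with its ground truth
#'
#' The trial table goes to `<path>.csv` (loader-identical schema) and the
#' ground truth to a `<path>.json` sidecar.
#'
#' @param rec Result of [generate_recording()].
#' @param path Output path stem.
#' @export
write_recording <- function(rec, path) {
  write_trial_table(rec$table, paste0(path, ".csv"))
  jsonlite::write_json(rec$ground_truth, paste0(path, ".json"),
                       dataframe = "rows", digits = NA)
  invisible(path)
}
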