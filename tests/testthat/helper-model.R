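# Shared fixtures, built once per test run.

.gsmv1_cache <- new.env(parent = emptyenv())

# Default bank and a model trained on the standard 10,000-patch 1/f ensemble
# (the study conditions); memoized because several files use it.
default_bank <- function() {
  if (is.null(.gsmv1_cache$bank))
    .gsmv1_cache$bank <- build_filterbank(filterbank_spec())
  .gsmv1_cache$bank
}

default_model <- function() {
  if (is.null(.gsmv1_cache$model))
    .gsmv1_cache$model <- train_gsm(default_bank(), "pink_texture",
                                    n_train = 10000L, seed = 101)
  .gsmv1_cache$model
}

# Random 2-D toy GSM parameter sets for oracle cross-checks.
toy_params_2d <- function(seed) {
  with_seed <- getFromNamespace("with_seed", "gsmv1")
  with_seed(seed, {
    A <- matrix(rnorm(4), 2)
    Cg <- crossprod(A) + diag(0.5, 2)
    gsm_params(Cg, diag(runif(1, 0.2, 0.5), 2))
  })
}

# Trial table with prescribed spike counts: each trial gets `count` spikes
# spread uniformly inside the counting window (latency 50, given duration).
table_from_counts <- function(counts_by_condition, neuron_id = "n1",
                              duration_ms = 200, meta = NULL,
                              baseline_n = 0L) {
  rows <- list()
  for (cid in names(counts_by_condition)) {
    cnts <- counts_by_condition[[cid]]
    trains <- lapply(seq_along(cnts), function(i) {
      n <- cnts[i]
      evoked <- if (n > 0) 50 + duration_ms * (seq_len(n) - 0.5) / n else numeric(0)
      if (baseline_n > 0)
        evoked <- c(-20 + 50 * (seq_len(baseline_n) - 0.5) / baseline_n, evoked)
      evoked
    })
    df <- data.frame(neuron_id = neuron_id, condition_id = cid,
                     trial = seq_along(cnts), spike_times = I(trains),
                     duration_ms = duration_ms, epoch_start_ms = -50,
                     epoch_end_ms = duration_ms + 100)
    if (!is.null(meta))
      for (col in names(meta)) df[[col]] <- meta[[col]][[cid]]
    rows[[cid]] <- df
  }
  trial_table(do.call(rbind, rows))
}

# Brute-force importance sampler over (nu, g) for the noisy GSM posterior:
# proposals from the prior, weights = Gaussian noise likelihood. Returns
# self-normalized estimates of E[g|x] and E[nu|x] with their Monte Carlo
# standard errors.
importance_oracle <- function(x, params, n = 2e5, seed = 1) {
  set.seed(seed)
  d <- params$dim
  nu <- params$mixer_scale * sqrt(-2 * log(runif(n)))
  L <- t(chol(params$C_g))
  g <- t(L %*% matrix(rnorm(d * n), d))
  resid <- matrix(x, n, d, byrow = TRUE) - nu * g
  Cni <- solve(params$C_noise)
  lw <- -0.5 * rowSums((resid %*% Cni) * resid)
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  est <- function(v) {
    m <- sum(w * v)
    list(mean = m, se = sqrt(sum(w^2 * (v - m)^2)))
  }
  gs <- lapply(seq_len(d), function(j) est(g[, j]))
  list(g_mean = vapply(gs, `[[`, numeric(1), "mean"),
       g_se = vapply(gs, `[[`, numeric(1), "se"),
       E_nu = est(nu)$mean, E_nu_se = est(nu)$se,
       ess = 1 / sum(w^2))
}
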