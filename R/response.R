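# Spike-count readout and the simulated experiments.

#' Convert feature samples to spike counts
#'
#' The default readout maps each posterior sample of the RF quadrature pair to
#' a count through the local oriented energy, `r = c * sqrt(g1+^2 + g1-^2)`;
#' `c` (spikes per unit feature magnitude) sets the overall response range.
#' The alternative `"expansive"` readout, `r = c * max(g1+, 0)^p`, is a
#' rectified expansive nonlinearity; the energy readout mispredicts the sign
#' of contrast effects on variance at fixed stimulus size, while size and
#' surround-orientation predictions are robust to the choice.
#'
#' Counts are kept continuous by default (the rounding error is negligible
#' for sufficiently large `c`); set `round = TRUE` for strict integer
#' semantics.
#'
#' @param g_plus,g_minus Samples of the odd/even RF features.
#' @param c Scaling factor, spikes per unit feature magnitude (> 0).
#' @param variant `"modulus"` (energy) or `"expansive"`.
#' @param expansive_p Exponent of the expansive readout.
#' @param round Round to integer counts.
#' @return Nonnegative spike counts, same length as the inputs.
#' @export
spike_transform <- function(g_plus, g_minus = NULL, c = 1,
                            variant = c("modulus", "expansive"),
                            expansive_p = 2, round = FALSE) {
  variant <- match.arg(variant)
  stopifnot(c > 0)
  r <- if (variant == "modulus") {
    stopifnot(!is.null(g_minus), length(g_minus) == length(g_plus))
    c * sqrt(g_plus^2 + g_minus^2)
  } else {
    c * pmax(g_plus, 0)^expansive_p
  }
  if (round) base::round(r) else r
}

#' Response statistics from a posterior
#'
#' Applies [spike_transform()] to every posterior sample and summarizes the
#' resulting across-trial spike counts: mean, unbiased variance, and Fano
#' factor (variance/mean; undefined and flagged when the mean is 0).
#'
#' @param posterior A [posterior_noisy()] object.
#' @param c,variant,expansive_p,round Passed to [spike_transform()].
#' @return Object of class `spike_response`: `r_samples`, `mean`, `variance`,
#'   `ff`, `ff_defined`, `c`, `variant`.
#' @export
response_stats <- function(posterior, c = 1, variant = "modulus",
                           expansive_p = 2, round = FALSE) {
  stopifnot(inherits(posterior, "gsm_posterior"),
            nrow(posterior$g_samples) >= 2)
  r <- spike_transform(posterior$g_samples[, 1], posterior$g_samples[, 2],
                       c = c, variant = variant, expansive_p = expansive_p,
                       round = round)
  m <- mean(r)
  v <- stats::var(r)
  structure(list(r_samples = r, mean = m, variance = v,
                 ff = if (m > 0) v / m else NA_real_,
                 ff_defined = m > 0, c = c, variant = variant),
            class = "spike_response")
}

boot_ci68 <- function(x, stat, n_boot = 1000L, seed = NULL) {
  with_seed(seed, {
    bs <- vapply(seq_len(n_boot),
                 function(i) stat(x[sample.int(length(x), replace = TRUE)]),
                 numeric(1))
    stats::quantile(bs, c(0.16, 0.84), names = FALSE, na.rm = TRUE)
  })
}

ff_stat <- function(r) {
  m <- mean(r)
  if (m > 0) stats::var(r) / m else NA_real_
}

# Shared worker: posterior + spike statistics for one stimulus condition.
condition_response <- function(model, image, c, variant, n_samples, seed,
                               n_boot = 1000L) {
  x <- apply_filterbank(model$bank, image)
  seeds <- child_seeds(seed, 3L)
  post <- posterior_noisy(x, model$params, n_samples = n_samples,
                          seed = seeds[[1]])
  resp <- response_stats(post, c = c, variant = variant)
  ci_m <- boot_ci68(resp$r_samples, mean, n_boot, seeds[[2]])
  ci_f <- boot_ci68(resp$r_samples, ff_stat, n_boot, seeds[[3]])
  list(x = x, post = post, resp = resp,
       row = data.frame(mean = resp$mean, variance = resp$variance,
                        ff = resp$ff,
                        mean_lo = ci_m[1], mean_hi = ci_m[2],
                        ff_lo = ci_f[1], ff_hi = ci_f[2],
                        lambda = post$lambda, E_nu = post$E_nu,
                        # deterministic posterior uncertainty of the encoded
                        # feature (grid moments, no Monte Carlo error)
                        g1_ff_exact = if (post$g_mean[1] > 0)
                          post$g_cov[1, 1] / post$g_mean[1] else NA_real_))
}

#' Mean-variance scan over an image ensemble
#'
#' Simulates the model neuron's response to every patch in an ensemble
#' (optionally pre-selecting patches with RF signal strength at or above the
#' ensemble median), then quantifies the across-image association between
#' spike-count mean and Fano factor: Pearson correlation with its two-sided
#' test against zero, and the linear-fit slope of FF on mean.
#'
#' @param model A [train_gsm()] model.
#' @param images 3-D array of patches (patch x patch x n).
#' @param c Spike scaling factor (default 2, the value used for broad natural
#'   ensembles).
#' @param variant Spike readout variant.
#' @param n_samples Posterior samples per image.
#' @param seed Integer seed.
#' @param select_rf_above_median Keep only patches with RF energy at or above
#'   the ensemble median before simulating.
#' @return List with `table` (one row per image: mean, variance, ff, lambda,
#'   rf_signal), `pearson_r`, `p_value`, `ff_slope`, `n_excluded`
#'   (images with undefined FF, excluded with a message).
#' @export
run_mean_variance_scan <- function(model, images, c = 2, variant = "modulus",
                                   n_samples = 400L, seed = NULL,
                                   select_rf_above_median = TRUE) {
  stopifnot(inherits(model, "gsm_model"), length(dim(images)) == 3L)
  X <- apply_filterbank(model$bank, images)
  sig <- rf_signal_strength(X)
  keep <- if (select_rf_above_median) sig >= stats::median(sig) else rep(TRUE, length(sig))
  X <- X[keep, , drop = FALSE]
  sig <- sig[keep]
  n <- nrow(X)
  seeds <- child_seeds(seed, n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    post <- posterior_noisy(X[i, ], model$params, n_samples = n_samples,
                            seed = seeds[[i]])
    resp <- response_stats(post, c = c, variant = variant)
    rows[[i]] <- data.frame(image = i, mean = resp$mean,
                            variance = resp$variance, ff = resp$ff,
                            lambda = post$lambda, rf_signal = sig[i])
  }
  tab <- do.call(rbind, rows)
  bad <- !is.finite(tab$ff)
  if (any(bad))
    message(sum(bad), " image(s) with undefined FF excluded from the correlation")
  ok <- tab[!bad, ]
  degenerate_inputs <- stats::sd(tab$lambda) < 1e-12 && stats::sd(tab$rf_signal) < 1e-12
  if (degenerate_inputs || stats::sd(ok$mean) == 0 || stats::sd(ok$ff) == 0) {
    warning("degenerate ensemble: across-image variance is zero, correlation undefined")
    ct <- list(estimate = NA_real_, p.value = NA_real_)
    slope <- NA_real_
  } else {
    ct <- stats::cor.test(ok$mean, ok$ff, method = "pearson")
    slope <- unname(stats::coef(stats::lm(ff ~ mean, data = ok))[2])
  }
  list(table = tab, pearson_r = unname(ct$estimate), p_value = ct$p.value,
       ff_slope = slope, n_excluded = sum(bad))
}

#' Size-tuning experiment
#'
#' Masks a base image at each aperture diameter and simulates the model
#' response. The mean spike count peaks for stimuli matched to the RF size and
#' is suppressed for larger ones, while the Fano factor keeps decreasing with
#' size: large stimuli raise the inferred global modulator (lambda increases
#' with size), which divisively shrinks posterior uncertainty.
#'
#' @param model A [train_gsm()] model.
#' @param base_image Full-field base image (matrix in the bank geometry).
#' @param diameters Aperture diameters in degrees, increasing; the default is
#'   the awake-experiment series.
#' @param c Spike scaling factor (default 15, the size-tuning value).
#' @param variant Spike readout variant.
#' @param n_samples Posterior samples per condition.
#' @param n_boot Bootstrap resamples for the 68% CIs.
#' @param seed Integer seed.
#' @return `data.frame` of class `gsm_tuning_curve`, one row per diameter:
#'   mean, ff, 68% bootstrap CIs, lambda, E_nu.
#' @export
run_size_tuning <- function(model, base_image,
                            diameters = c(0.34, 0.55, 0.90, 2.4, 3.8),
                            c = 15, variant = "modulus", n_samples = 400L,
                            n_boot = 1000L, seed = NULL) {
  stopifnot(inherits(model, "gsm_model"), length(diameters) >= 3,
            !is.unsorted(diameters, strictly = TRUE))
  spec <- model$bank$spec
  seeds <- child_seeds(seed, length(diameters))
  rows <- vector("list", length(diameters))
  for (i in seq_along(diameters)) {
    img <- apply_circular_mask(spec, base_image, diameters[i])
    cr <- condition_response(model, img, c, variant, n_samples, seeds[[i]], n_boot)
    rows[[i]] <- cbind(data.frame(size_deg = diameters[i]), cr$row)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("gsm_tuning_curve", class(out))
  attr(out, "seed") <- seed
  attr(out, "n_samples") <- n_samples
  out
}

#' Surround-orientation tuning experiment
#'
#' Simulates the response to a center grating alone and to compound gratings
#' with an annular surround at each requested orientation. A matched surround
#' drives the same-orientation surround filters, raising the inferred global
#' modulator and suppressing both the mean count and the Fano factor more
#' than an orthogonal surround does.
#'
#' @param model A [train_gsm()] model.
#' @param center_diameter Center disc diameter, degrees.
#' @param surround_orientations Surround stripe orientations, degrees
#'   (absolute; the center uses the bank orientation).
#' @param surround_inner,surround_outer Annulus diameters, degrees.
#' @param c Spike scaling factor (default 40, the surround-tuning value).
#' @param variant Spike readout variant.
#' @param n_samples Posterior samples per condition.
#' @param n_boot Bootstrap resamples for the 68% CIs.
#' @param seed Integer seed.
#' @return `data.frame` of class `gsm_tuning_curve`, one row per condition
#'   (`"center_alone"` first, then one per surround orientation), with
#'   columns as in [run_size_tuning()] plus `condition` and
#'   `surround_orientation`.
#' @export
run_surround_orientation <- function(model, center_diameter = 0.9,
                                     surround_orientations = NULL,
                                     surround_inner = 1.1,
                                     surround_outer = 3.8,
                                     c = 40, variant = "modulus",
                                     n_samples = 400L, n_boot = 1000L,
                                     seed = NULL) {
  stopifnot(inherits(model, "gsm_model"))
  spec <- model$bank$spec
  if (is.null(surround_orientations))
    surround_orientations <- spec$orientation + c(0, 45, 90, 135)
  seeds <- child_seeds(seed, length(surround_orientations) + 1L)
  imgs <- c(list(make_grating(spec, center_diameter)),
            lapply(surround_orientations, function(o)
              make_compound_grating(spec, center_diameter, surround_inner,
                                    surround_outer, surround_orientation = o)))
  labels <- c("center_alone",
              sprintf("surround_%g", surround_orientations))
  rows <- vector("list", length(imgs))
  for (i in seq_along(imgs)) {
    cr <- condition_response(model, imgs[[i]], c, variant, n_samples,
                             seeds[[i]], n_boot)
    rows[[i]] <- cbind(data.frame(condition = labels[i],
                                  surround_orientation =
                                    if (i == 1) NA_real_ else surround_orientations[i - 1]),
                       cr$row)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("gsm_tuning_curve", class(out))
  attr(out, "seed") <- seed
  attr(out, "n_samples") <- n_samples
  out
}
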