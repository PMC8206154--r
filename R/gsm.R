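# The Gaussian scale mixture (GSM) generative model and its analytic
# (noiseless) posterior summaries.
#
# Generative model:  x = nu * g + eta
#   g   ~ N(0, C_g)           local oriented features (what the neuron encodes)
#   nu  ~ Rayleigh(sigma)     positive scalar global modulator ("mixer")
#   eta ~ N(0, C_noise)       observation noise
#
# The mixer prior is parametrized by its Rayleigh scale (default sigma = 1),
# the parametrization in which the large-lambda posterior expansions
# E[nu|x] = sqrt(lambda), E[g1+|x] = x1+/sqrt(lambda) and
# FF[g1+|x] = x1+/(4*lambda^(3/2)) are exact to O(1/lambda). Rescaling sigma
# is equivalent to rescaling C_g (the generative model is unchanged up to
# relabeling of nu and g), so sigma is exposed but rarely worth changing.

#' Construct a GSM parameter set
#'
#' @param C_g Symmetric positive-definite feature covariance.
#' @param C_noise Symmetric positive-semidefinite observation-noise
#'   covariance (same dimension as `C_g`).
#' @param mixer_scale Rayleigh scale of the mixer prior (default 1; the prior
#'   mean is `mixer_scale * sqrt(pi/2)` and `E[nu^2] = 2 * mixer_scale^2`).
#' @param provenance Optional list recording how the parameters were obtained
#'   (training kind, seed, bank spec, data hash).
#' @return Object of class `gsm_params`.
#' @export
gsm_params <- function(C_g, C_noise = NULL, mixer_scale = 1, provenance = NULL) {
  stop_if_not_matrix(C_g, "C_g")
  d <- nrow(C_g)
  if (is.null(C_noise)) C_noise <- matrix(0, d, d)
  stop_if_not_matrix(C_noise, "C_noise")
  stopifnot(nrow(C_noise) == d, mixer_scale > 0)
  C_g <- symmetrize(C_g)
  C_noise <- symmetrize(C_noise)
  ev <- eigen(C_g, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("C_g must be positive definite (use pd_floor/train_moment_matching)",
         call. = FALSE)
  if (!is_psd(C_noise))
    stop("C_noise must be positive semidefinite", call. = FALSE)
  structure(list(C_g = C_g, C_noise = C_noise, mixer_scale = mixer_scale,
                 dim = d, provenance = provenance),
            class = "gsm_params")
}

#' @export
print.gsm_params <- function(x, ...) {
  cat(sprintf("GSM parameters: %d features, Rayleigh(scale=%g) mixer\n",
              x$dim, x$mixer_scale))
  cat(sprintf("  tr(C_g) = %.4g, tr(C_noise) = %.4g\n",
              sum(diag(x$C_g)), sum(diag(x$C_noise))))
  invisible(x)
}

#' Train the feature covariance by moment matching
#'
#' Under the GSM, `cov(x) = E[nu^2] * C_g + C_noise`; training images are
#' treated as noise-free, so `C_g` is the empirical covariance of filter
#' outputs divided by the mixer second moment `E[nu^2] = 2 * mixer_scale^2`.
#' The result is symmetrized and eigenvalue-floored to positive definiteness.
#'
#' @param filter_outputs N-by-d matrix of filter responses, one row per
#'   training patch.
#' @param mixer_scale Rayleigh scale of the mixer prior.
#' @param min_n Minimum number of training patches.
#' @param floor_frac Eigenvalue floor as a fraction of the largest eigenvalue.
#' @return d-by-d positive-definite covariance matrix.
#' @export
train_moment_matching <- function(filter_outputs, mixer_scale = 1,
                                  min_n = 1000L, floor_frac = 1e-8) {
  stopifnot(is.matrix(filter_outputs), all(is.finite(filter_outputs)))
  if (nrow(filter_outputs) < min_n)
    stop(sprintf("need at least %d training patches, got %d",
                 min_n, nrow(filter_outputs)), call. = FALSE)
  C <- stats::cov(filter_outputs) / (2 * mixer_scale^2)
  pd_floor(C, floor_frac)
}

#' Estimate the observation-noise covariance from white-noise patches
#'
#' Applies the bank to `n_patches` i.i.d. Gaussian pixel-noise patches
#' (pixel standard deviation `pixel_sd`) and scales the empirical output
#' covariance by `scale` (heuristic default 0.1), giving a noise term that
#' keeps model responses and variability non-zero for weak inputs.
#'
#' @param bank A [build_filterbank()] object.
#' @param n_patches Number of white-noise patches (generated in chunks).
#' @param scale Multiplier applied to the empirical covariance.
#' @param pixel_sd Pixel noise standard deviation; match it to the RMS
#'   luminance of the training ensemble (1 for standardized ensembles).
#' @param seed Integer seed.
#' @return Positive-semidefinite covariance matrix.
#' @export
estimate_noise_cov <- function(bank, n_patches = 10000L, scale = 0.1,
                               pixel_sd = 1, seed = NULL) {
  stopifnot(inherits(bank, "filterbank"), n_patches >= 100, scale >= 0,
            pixel_sd > 0)
  X <- filter_output_ensemble(bank, "white_noise", n_patches, seed,
                              standardize = FALSE) * pixel_sd
  symmetrize(scale * stats::cov(X))
}

# Filter outputs over a seeded texture ensemble, generated in chunks to bound
# memory; with standardize = TRUE outputs are rescaled by the ensemble RMS
# luminance (a linear operation, so chunking is exact).
filter_output_ensemble <- function(bank, kind, n, seed = NULL,
                                   standardize = TRUE, chunk = 1000L) {
  spec <- bank$spec
  seeds <- child_seeds(seed, ceiling(n / chunk))
  X <- matrix(NA_real_, n, ncol(bank$K))
  ss <- 0
  npix <- 0
  done <- 0L
  for (i in seq_along(seeds)) {
    m <- min(chunk, n - done)
    a <- make_texture_ensemble(spec, kind, m, seeds[[i]], standardize = FALSE)
    X[done + seq_len(m), ] <- apply_filterbank(bank, a)
    ss <- ss + sum(a^2)
    npix <- npix + length(a)
    done <- done + m
  }
  if (standardize) {
    rms <- sqrt(ss / npix)
    if (rms > 0) X <- X / rms
  }
  X
}

#' Train a complete GSM model
#'
#' Convenience wrapper: builds (or reuses) the filter bank, computes filter
#' outputs over a training ensemble, moment-matches `C_g`, and estimates
#' `C_noise` from white-noise patches.
#'
#' @param bank A [build_filterbank()] object.
#' @param train_kind Training ensemble: `"pink_texture"` (1/f surrogate for
#'   natural patches) or `"white_noise"`.
#' @param n_train Number of training patches.
#' @param noise_scale Scale of the white-noise covariance used for `C_noise`.
#' @param n_noise Number of white-noise patches for the noise estimate.
#' @param mixer_scale Rayleigh scale of the mixer prior.
#' @param seed Integer seed controlling both ensembles.
#' @return Object of class `gsm_model`: list with `bank` and `params`.
#' @export
train_gsm <- function(bank, train_kind = c("pink_texture", "white_noise"),
                      n_train = 10000L, noise_scale = 0.1, n_noise = 10000L,
                      mixer_scale = 1, seed = NULL) {
  train_kind <- match.arg(train_kind)
  seeds <- child_seeds(seed, 2L)
  X <- filter_output_ensemble(bank, train_kind, n_train, seeds[[1]])
  C_g <- train_moment_matching(X, mixer_scale = mixer_scale)
  C_noise <- estimate_noise_cov(bank, n_noise, noise_scale, pixel_sd = 1,
                                seed = seeds[[2]])
  params <- gsm_params(C_g, C_noise, mixer_scale,
                       provenance = list(train_kind = train_kind,
                                         n_train = n_train,
                                         noise_scale = noise_scale,
                                         n_noise = n_noise,
                                         seed = seed))
  structure(list(bank = bank, params = params), class = "gsm_model")
}

#' The divisive-normalization signal lambda
#'
#' `lambda = sqrt(x' C_g^{-1} x)`, the quadratic-form norm of the filter
#' outputs under the feature covariance. For large lambda it is the posterior
#' estimate of the global modulator, and it divides both the posterior mean
#' (by `sqrt(lambda)`) and variance (by `lambda^2`) of the encoded feature —
#' the model's divisive normalization.
#'
#' @param x Filter response vector.
#' @param C_g Positive-definite feature covariance.
#' @return Nonnegative scalar.
#' @export
lambda_stat <- function(x, C_g) {
  stop_if_not_matrix(C_g, "C_g")
  stopifnot(length(x) == nrow(C_g), all(is.finite(x)))
  R <- tryCatch(chol(symmetrize(C_g)),
                error = function(e) stop("C_g is not positive definite", call. = FALSE))
  sqrt(sum(backsolve(R, x, transpose = TRUE)^2))
}

#' Exact 1-D noiseless posterior by numeric integration
#'
#' For the scalar noiseless model `x = nu * g`, the posterior over the mixer
#' is `p(nu|x) \propto Rayleigh(nu; sigma) * N(x; 0, nu^2 c_g)` and `g = x/nu`
#' deterministically given `nu`. Posterior moments of `g` follow by quadrature
#' over a wide logarithmic grid in `nu`. This is the independent oracle against
#' which the asymptotic forms are validated.
#'
#' @param x Scalar observation.
#' @param c_g Scalar feature variance.
#' @param mixer_scale Rayleigh scale of the mixer prior.
#' @param n_grid Number of quadrature nodes.
#' @return List with `mean`, `variance`, `ff` (of g given x), and `E_nu`.
#' @export
noiseless_posterior_1d <- function(x, c_g = 1, mixer_scale = 1, n_grid = 20000L) {
  stopifnot(length(x) == 1, is.finite(x), c_g > 0)
  lam <- abs(x) / sqrt(c_g)
  if (lam == 0) return(list(mean = 0, variance = 0, ff = NA_real_, E_nu = NA_real_))
  lo <- min(qrayleigh(1e-10, mixer_scale), sqrt(lam) / 100)
  hi <- max(qrayleigh(1 - 1e-12, mixer_scale), 20 * sqrt(lam))
  nu <- exp(seq(log(lo), log(hi), length.out = n_grid))
  # log p(nu|x) up to a constant: log prior + log N(x; 0, nu^2 c_g)
  lp <- drayleigh(nu, mixer_scale, log = TRUE) - log(nu) - x^2 / (2 * nu^2 * c_g)
  lp <- lp - max(lp)
  dnu <- c(diff(nu), 0)
  w <- exp(lp) * dnu
  w <- w / sum(w)
  Einv <- sum(w / nu)
  Einv2 <- sum(w / nu^2)
  m <- x * Einv
  v <- x^2 * max(Einv2 - Einv^2, 0)
  list(mean = m, variance = v, ff = if (m != 0) v / m else NA_real_,
       E_nu = sum(w * nu))
}

#' Asymptotic noiseless posterior summary of the encoded feature
#'
#' Large-lambda closed forms for the noiseless GSM posterior of the RF-odd
#' feature g1+: `E[g1+|x] = x1+/sqrt(lambda)`,
#' `FF[g1+|x] = x1+/(4*lambda^(3/2))`, and mixer estimate
#' `E[nu|x] = sqrt(lambda)`, each exact up to relative corrections of order
#' `1/lambda`. A warning is issued below `lambda_min` where the corrections
#' are no longer negligible, and the forms are flagged inapplicable for
#' `x1+ <= 0` (they assume an input in phase with the odd filter).
#'
#' @param x Filter response vector (x\[1\] = x1+).
#' @param C_g Positive-definite feature covariance.
#' @param lambda_min Threshold below which a regime warning is issued.
#' @return List with `g1_mean`, `g1_ff`, `mixer_estimate` (= sqrt(lambda)),
#'   `lambda`, and `applicable` (FALSE when x1+ <= 0).
#' @export
noiseless_posterior_summary <- function(x, C_g, lambda_min = 5) {
  lam <- lambda_stat(x, C_g)
  applicable <- is.finite(x[1]) && x[1] > 0
  if (!applicable)
    warning("asymptotic forms assume x1+ > 0; values flagged inapplicable")
  else if (lam < lambda_min)
    warning(sprintf("lambda = %.3g < %.3g: asymptotic O(1/lambda) corrections may be large",
                    lam, lambda_min))
  list(g1_mean = if (applicable) x[1] / sqrt(lam) else NA_real_,
       g1_ff = if (applicable) x[1] / (4 * lam * sqrt(lam)) else NA_real_,
       mixer_estimate = sqrt(lam),
       lambda = lam,
       applicable = applicable)
}

#' Admissible feature interval under the noiseless constraint
#'
#' In the 1-D noiseless model the observation pins `nu * g = x`, so a mixer
#' confined to `[nu_min, nu_max]` confines the feature to
#' `[x/nu_max, x/nu_min]`: a larger inferred modulator shrinks both the mean
#' and the spread of the encoded feature.
#'
#' @param x Positive scalar observation.
#' @param nu_min,nu_max Mixer interval bounds, `0 < nu_min <= nu_max`.
#' @return Numeric vector `c(g_min, g_max)`.
#' @export
mixer_constraint_interval <- function(x, nu_min, nu_max) {
  stopifnot(x > 0, nu_min > 0, nu_max >= nu_min)
  c(g_min = x / nu_max, g_max = x / nu_min)
}

#' Additive-modulator control model (1-D)
#'
#' Gaussian posterior of `g` in the additive model `x = g + nu + eta` with
#' independent zero-mean Gaussian terms. Because everything is jointly
#' Gaussian, the posterior variance of `g` is independent of `x`: an additive
#' modulator moves only the inferred mean, never the uncertainty. This is the
#' control showing that the mean-variance coupling of the GSM requires the
#' multiplicative interaction.
#'
#' @param x Scalar observation.
#' @param g_sd,offset_sd,noise_sd Prior standard deviations of `g`, the
#'   additive modulator, and the noise.
#' @return List with `mean` and `variance` of the posterior over `g`.
#' @export
additive_control_posterior_1d <- function(x, g_sd, offset_sd, noise_sd) {
  stopifnot(g_sd > 0, offset_sd > 0, noise_sd > 0)
  tot <- g_sd^2 + offset_sd^2 + noise_sd^2
  list(mean = x * g_sd^2 / tot,
       variance = g_sd^2 * (offset_sd^2 + noise_sd^2) / tot)
}
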