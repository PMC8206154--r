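# Posterior inference for the noisy GSM.
#
# Because the mixer nu is scalar, marginalization is exactly one-dimensional:
# p(nu | x) is computed on a log-spaced grid over the prior's quantile range
# (auto-widened until the posterior tail mass is negligible), and g | nu, x is
# the conditional Gaussian
#   mean  nu * C_g (nu^2 C_g + C_noise)^{-1} x
#   cov   C_g - nu^2 C_g (nu^2 C_g + C_noise)^{-1} C_g.
# Sampling is therefore Rao-Blackwellized: draw nu from the grid weights, then
# one exact Gaussian draw of g per nu. No burn-in or convergence diagnostics
# are needed, unlike an MCMC sampler, and exact grid moments of g (law of
# total expectation/variance over the nu grid) come for free.

# Joint whitening of (C_g, C_noise): with L = lower Cholesky of C_noise and
# W = L^-1 C_g L^-T = Q D Q', every nu-dependent quantity reduces to O(d)
# work per grid point via B = L^-T Q.
gsm_decomposition <- function(params) {
  d <- params$dim
  Cn <- params$C_noise
  # floor a (near-)singular noise covariance so the conditional is proper
  jitter <- 1e-10 * mean(diag(params$C_g))
  ev <- eigen(symmetrize(Cn), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < jitter) Cn <- symmetrize(Cn) + diag(jitter, d)
  L <- t(chol(Cn))
  Li <- forwardsolve(L, diag(d))
  W <- symmetrize(Li %*% params$C_g %*% t(Li))
  e <- eigen(W, symmetric = TRUE)
  B <- t(Li) %*% e$vectors          # (nu^2 C_g + C_noise)^{-1} = B diag(1/(nu^2 d + 1)) B'
  list(B = B, d_eig = pmax(e$values, 0), A = params$C_g %*% B,
       logdet_noise = 2 * sum(log(diag(L))))
}

# log p(x | nu) over a vector of nu values, up to an x-independent constant.
loglik_nu <- function(u, d_eig, nu) {
  nu2 <- nu^2
  den <- outer(d_eig, nu2) + 1            # d x n_grid
  -0.5 * (colSums(u^2 / den) + colSums(log(den)))
}

#' Posterior over the mixer and local features for one input
#'
#' Computes `p(nu | x)` exactly (to grid resolution) by scalar marginalization,
#' the exact posterior mean and covariance of `g | x` by integrating the
#' conditional Gaussian moments over the grid, and `n_samples` joint posterior
#' draws of `(nu, g)` used as the model neuron's across-trial responses.
#'
#' The grid is log-spaced over the mixer prior's `[1e-4, 1 - 1e-8]` quantile
#' range and widened automatically (upper bound doubled) while the posterior
#' mass in the top grid points exceeds `tail_tol`; inputs so strong that
#' widening fails raise an error.
#'
#' @param x Filter response vector.
#' @param params A [gsm_params()] object.
#' @param n_samples Number of posterior draws (default 400, the number of
#'   samples used for all simulated-experiment statistics).
#' @param seed Integer seed, recorded in the result.
#' @param n_grid Number of grid points for the mixer marginalization.
#' @param tail_tol Maximum tolerated posterior mass in the top 5 grid points.
#' @return Object of class `gsm_posterior`: `nu_grid`, `weights`, `E_nu`,
#'   `g_mean` and `g_cov` (exact grid moments), `nu_samples`,
#'   `g_samples` (`n_samples` x d), `lambda`, `seed`.
#' @export
posterior_noisy <- function(x, params, n_samples = 400L, seed = NULL,
                            n_grid = 2000L, tail_tol = 1e-6) {
  stopifnot(inherits(params, "gsm_params"), length(x) == params$dim,
            all(is.finite(x)), n_samples >= 1, n_grid >= 50)
  dec <- gsm_decomposition(params)
  u <- drop(crossprod(dec$B, x))
  lo <- qrayleigh(1e-4, params$mixer_scale)
  hi <- qrayleigh(1 - 1e-8, params$mixer_scale)
  for (iter in seq_len(60L)) {
    nu <- exp(seq(log(lo), log(hi), length.out = n_grid))
    lp <- loglik_nu(u, dec$d_eig, nu) + drayleigh(nu, params$mixer_scale, log = TRUE)
    lp <- lp - max(lp)
    w <- exp(lp) * c(diff(nu), diff(nu)[n_grid - 1L])   # trapezoid-style widths
    w <- w / sum(w)
    if (sum(w[(n_grid - 4L):n_grid]) <= tail_tol) break
    hi <- hi * 2
    if (iter == 60L)
      stop("mixer grid could not be widened to capture the posterior tail",
           call. = FALSE)
  }
  # exact grid moments of g | x
  nu2 <- nu^2
  den <- outer(dec$d_eig, nu2) + 1                       # d x n_grid
  Mcond <- dec$A %*% (matrix(nu, params$dim, n_grid, byrow = TRUE) * (u / den))
  g_mean <- drop(Mcond %*% w)
  s_k <- drop((matrix(nu2, params$dim, n_grid, byrow = TRUE) / den) %*% w)  # E_w[nu^2/(nu^2 d_k + 1)]
  Ecov <- params$C_g - dec$A %*% (s_k * t(dec$A))
  Cmeans <- Mcond %*% (w * t(Mcond)) - tcrossprod(g_mean)
  g_cov <- symmetrize(Ecov + Cmeans)
  E_nu <- sum(w * nu)

  samp <- with_seed(seed, {
    idx <- sample.int(n_grid, n_samples, replace = TRUE, prob = w)
    g <- matrix(NA_real_, n_samples, params$dim)
    for (j in unique(idx)) {
      rows <- which(idx == j)
      cv <- params$C_g - dec$A %*% ((nu2[j] / den[, j]) * t(dec$A))
      R <- chol(symmetrize(cv) + diag(1e-12 * mean(diag(params$C_g)), params$dim))
      z <- matrix(stats::rnorm(length(rows) * params$dim), length(rows))
      g[rows, ] <- rep(Mcond[, j], each = length(rows)) + z %*% R
    }
    list(nu = nu[idx], g = g)
  })
  structure(list(nu_grid = nu, weights = w, E_nu = E_nu,
                 g_mean = g_mean, g_cov = g_cov,
                 nu_samples = samp$nu, g_samples = samp$g,
                 lambda = lambda_stat(x, params$C_g),
                 n_samples = as.integer(n_samples), seed = seed),
            class = "gsm_posterior")
}

#' @export
print.gsm_posterior <- function(x, ...) {
  cat(sprintf("GSM posterior: lambda = %.3g, E[nu|x] = %.3g, %d samples\n",
              x$lambda, x$E_nu, x$n_samples))
  cat(sprintf("  E[g1+|x] = %.4g, sd[g1+|x] = %.4g\n",
              x$g_mean[1], sqrt(x$g_cov[1, 1])))
  invisible(x)
}
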