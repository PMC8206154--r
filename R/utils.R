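# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All exported stochastic operations funnel through this, so a seed given to
# any one of them never perturbs the session RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else suppressWarnings(rm(".Random.seed", envir = env))
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream of child seeds from one user-facing seed, kept within the
# 32-bit integer range R requires.
child_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_if_not_matrix <- function(m, name, square = TRUE) {
  if (!is.matrix(m) || !is.numeric(m) || anyNA(m) || any(!is.finite(m)))
    stop(sprintf("'%s' must be a finite numeric matrix", name), call. = FALSE)
  if (square && nrow(m) != ncol(m))
    stop(sprintf("'%s' must be square", name), call. = FALSE)
  invisible(m)
}

symmetrize <- function(m) (m + t(m)) / 2

# Repair a symmetric matrix to positive definiteness by flooring its
# eigenvalues at `floor_frac` times the largest one.
pd_floor <- function(m, floor_frac = 1e-8) {
  m <- symmetrize(m)
  e <- eigen(m, symmetric = TRUE)
  mx <- max(e$values)
  if (!is.finite(mx) || mx <= 0)
    stop("matrix has no positive eigenvalue; cannot repair to positive definite",
         call. = FALSE)
  v <- pmax(e$values, floor_frac * mx)
  symmetrize(e$vectors %*% (v * t(e$vectors)))
}

is_psd <- function(m, tol = 1e-8) {
  e <- eigen(symmetrize(m), symmetric = TRUE, only.values = TRUE)$values
  min(e) >= -tol * max(abs(e), 1e-300)
}

# Rayleigh distribution with scale parameter `sigma` (density and quantiles).
drayleigh <- function(x, sigma = 1, log = FALSE) {
  lp <- ifelse(x > 0, log(x) - 2 * log(sigma) - x^2 / (2 * sigma^2), -Inf)
  if (log) lp else exp(lp)
}

qrayleigh <- function(p, sigma = 1) sigma * sqrt(-2 * log1p(-p))

`%||%` <- function(a, b) if (is.null(a)) b else a
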