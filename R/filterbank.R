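#' Specify the oriented quadrature filter bank
#'
#' The model receptive field (RF) and its surround are defined by 9 quadrature
#' pairs of oriented Gabor filters: one pair at the patch center (the RF) and
#' eight pairs uniformly spaced on a ring around it, all sharing one
#' orientation. The ring radius is chosen so the surround envelopes slightly
#' overlap the center envelope, mirroring the partial overlap of suppressive
#' surround mechanisms with V1 RFs.
#'
#' Coordinate convention: the image is a numeric matrix in row-major display
#' order; the origin is at the patch center, the x axis points along columns
#' (rightward), the y axis along decreasing row index (upward), and angles are
#' measured counterclockwise from the horizontal axis. `orientation` is the
#' orientation of the filter stripes (90 = vertical).
#'
#' @param patch_size_px Side of the square patch, pixels.
#' @param deg_per_px Degrees of visual angle per pixel.
#' @param orientation Stripe orientation of all filters, degrees
#'   counterclockwise from horizontal.
#' @param spatial_frequency Carrier frequency, cycles/degree.
#' @param envelope_sd Gaussian envelope standard deviation, degrees.
#' @param surround_ring_radius Distance of surround filter centers from the
#'   patch center, degrees.
#' @param n_surround_positions Number of surround quadrature pairs on the ring.
#' @return An object of class `filterbank_spec`.
#' @examples
#' spec <- filterbank_spec()
#' spec$patch_size_px
#' @export
filterbank_spec <- function(patch_size_px = 80L,
                            deg_per_px = 0.05,
                            orientation = 90,
                            spatial_frequency = 1,
                            envelope_sd = 0.2,
                            surround_ring_radius = 0.5,
                            n_surround_positions = 8L) {
  stopifnot(patch_size_px > 0, deg_per_px > 0, spatial_frequency > 0,
            envelope_sd > 0, surround_ring_radius > 0,
            n_surround_positions >= 1)
  # surround envelopes must overlap the center envelope (overlap fraction > 0)
  if (surround_ring_radius >= 6 * envelope_sd)
    stop("surround ring radius too large: surround envelopes must overlap the center envelope",
         call. = FALSE)
  structure(list(patch_size_px = as.integer(patch_size_px),
                 deg_per_px = deg_per_px,
                 orientation = orientation,
                 spatial_frequency = spatial_frequency,
                 envelope_sd = envelope_sd,
                 surround_ring_radius = surround_ring_radius,
                 n_surround_positions = as.integer(n_surround_positions)),
            class = "filterbank_spec")
}

# Pixel-center coordinates in degrees: x rightward along columns, y upward.
patch_coords <- function(spec) {
  n <- spec$patch_size_px
  ctr <- (n + 1) / 2
  x <- ((seq_len(n) - ctr)) * spec$deg_per_px
  list(x = matrix(rep(x, each = n), n, n),          # constant along rows
       y = matrix(rep(rev(x), times = n), n, n))    # decreasing with row index
}

patch_half_extent <- function(spec) spec$patch_size_px * spec$deg_per_px / 2

gabor_kernel <- function(spec, x0, y0, phase = c("odd", "even")) {
  phase <- match.arg(phase)
  co <- patch_coords(spec)
  dx <- co$x - x0
  dy <- co$y - y0
  # carrier varies perpendicular to the stripes
  a <- (spec$orientation - 90) * pi / 180
  t <- dx * cos(a) + dy * sin(a)
  env <- exp(-(dx^2 + dy^2) / (2 * spec$envelope_sd^2))
  carrier <- if (phase == "odd") sin(2 * pi * spec$spatial_frequency * t)
             else                cos(2 * pi * spec$spatial_frequency * t)
  k <- env * carrier
  k <- k - mean(k)               # DC-free
  k / sqrt(sum(k^2))             # unit L2 norm
}

#' Build the 18-filter oriented quadrature bank
#'
#' Constructs the kernels deterministically from a [filterbank_spec()]:
#' center-odd, center-even, then for each surround position (angles 2*pi*k/8,
#' k = 0..7, counterclockwise from horizontal) the odd and even kernels. Every
#' kernel is DC-free and L2-normalized, so filter outputs are comparable
#' across positions and the white-noise output covariance is well conditioned.
#'
#' @param spec A [filterbank_spec()].
#' @return An object of class `filterbank`: list with `kernels` (list of 18
#'   matrices), `K` (pixels-by-18 matrix of vectorized kernels), `labels`,
#'   and `spec`.
#' @export
build_filterbank <- function(spec = filterbank_spec()) {
  stopifnot(inherits(spec, "filterbank_spec"))
  half <- patch_half_extent(spec)
  if (spec$surround_ring_radius + 2 * spec$envelope_sd > half)
    stop("patch too small to hold the surround ring and its envelopes; ",
         "increase patch_size_px or deg_per_px", call. = FALSE)
  centers <- rbind(c(0, 0))
  ang <- 2 * pi * (seq_len(spec$n_surround_positions) - 1) / spec$n_surround_positions
  centers <- rbind(centers,
                   cbind(spec$surround_ring_radius * cos(ang),
                         spec$surround_ring_radius * sin(ang)))
  kernels <- list()
  labels <- character(0)
  for (i in seq_len(nrow(centers))) {
    pos <- if (i == 1) "center" else sprintf("surround%d", i - 2)
    for (ph in c("odd", "even")) {
      kernels[[length(kernels) + 1L]] <-
        gabor_kernel(spec, centers[i, 1], centers[i, 2], ph)
      labels <- c(labels, paste0(pos, "_", ph))
    }
  }
  K <- vapply(kernels, as.vector, numeric(spec$patch_size_px^2))
  structure(list(kernels = kernels, K = K, labels = labels,
                 centers_deg = centers, spec = spec),
            class = "filterbank")
}

#' Apply the filter bank to an image patch
#'
#' Each filter output is the inner product of its kernel with the luminance
#' patch; the result is the observable vector x of the generative model,
#' ordered as the bank (x\[1\] = center-odd = x1+, x\[2\] = center-even = x1-).
#'
#' @param bank A [build_filterbank()] object.
#' @param image Numeric matrix with the bank's patch dimensions, or a
#'   3-D array of stacked patches (patch x patch x n).
#' @return Numeric vector of length 18, or an n-by-18 matrix for an array
#'   input.
#' @export
apply_filterbank <- function(bank, image) {
  stopifnot(inherits(bank, "filterbank"))
  n <- bank$spec$patch_size_px
  if (is.matrix(image)) {
    if (!all(dim(image) == c(n, n)))
      stop(sprintf("image is %dx%d but the bank expects %dx%d",
                   nrow(image), ncol(image), n, n), call. = FALSE)
    drop(crossprod(bank$K, as.vector(image)))
  } else if (length(dim(image)) == 3L) {
    if (!all(dim(image)[1:2] == c(n, n)))
      stop("patch dimensions do not match the bank", call. = FALSE)
    m <- dim(image)[3]
    t(crossprod(bank$K, matrix(image, n * n, m)))
  } else {
    stop("image must be a matrix or a 3-D array of patches", call. = FALSE)
  }
}

#' Signal strength inside the model receptive field
#'
#' The local oriented energy captured by the center quadrature pair,
#' x1+^2 + x1-^2. Used to select image patches with sufficient RF drive
#' (above the ensemble median).
#'
#' @param x Length-18 filter response vector, or an n-by-18 matrix of
#'   responses (one row per patch).
#' @return Scalar (or vector) of RF energies.
#' @export
rf_signal_strength <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) >= 2)
    x[, 1]^2 + x[, 2]^2
  } else {
    stopifnot(length(x) >= 2, all(is.finite(x[1:2])))
    x[1]^2 + x[2]^2
  }
}
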