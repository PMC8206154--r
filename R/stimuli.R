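# Stimulus generation: windowed gratings, compound center-surround gratings,
# texture ensembles (white noise / 1/f "pink" surrogates for natural patches),
# and loaders for real image patches.
#
# Luminance convention: images are numeric matrices centered on 0 (the
# mean-luminance gray background). Gratings at contrast 1 have amplitude 1;
# texture ensembles are standardized to unit root-mean-square luminance across
# the ensemble, so grating and texture inputs live on a comparable scale.

#' Circular aperture mask for a patch geometry
#'
#' @param spec A [filterbank_spec()] fixing patch size and degrees/pixel.
#' @param diameter Aperture diameter, degrees.
#' @return Logical matrix, TRUE inside the (hard-edged) aperture.
#' @export
aperture_mask <- function(spec, diameter) {
  stopifnot(diameter > 0)
  if (diameter / 2 > patch_half_extent(spec) + 1e-12)
    stop(sprintf("aperture diameter %.3g deg exceeds the %.3g deg patch",
                 diameter, 2 * patch_half_extent(spec)), call. = FALSE)
  co <- patch_coords(spec)
  sqrt(co$x^2 + co$y^2) <= diameter / 2
}

#' Apply a hard circular window to an image
#'
#' Pixels outside the aperture are set to the background gray level.
#'
#' @inheritParams aperture_mask
#' @param image Numeric matrix in the spec's patch geometry.
#' @param background Background luminance (default 0 = mean gray).
#' @export
apply_circular_mask <- function(spec, image, diameter, background = 0) {
  m <- aperture_mask(spec, diameter)
  out <- matrix(background, nrow(image), ncol(image))
  out[m] <- image[m]
  out
}

grating_field <- function(spec, orientation, spatial_frequency, phase, contrast) {
  co <- patch_coords(spec)
  a <- (orientation - 90) * pi / 180   # carrier axis, perpendicular to stripes
  t <- co$x * cos(a) + co$y * sin(a)
  contrast * sin(2 * pi * spatial_frequency * t + phase * pi / 180)
}

#' Sinusoidal grating in a hard circular aperture
#'
#' A static grating on mean-gray background, masked by a hard-edged circular
#' window (no taper). At `phase = 0` and the bank's orientation and frequency,
#' the grating is spatially in phase with the odd (sine) center filter.
#'
#' @param spec A [filterbank_spec()] fixing the patch geometry.
#' @param diameter Aperture diameter, degrees.
#' @param orientation Stripe orientation, degrees counterclockwise from
#'   horizontal.
#' @param spatial_frequency Cycles/degree.
#' @param phase Spatial phase, degrees.
#' @param contrast Amplitude as a fraction of full scale, in \[0, 1\].
#' @param background Background luminance.
#' @return Numeric patch matrix.
#' @export
make_grating <- function(spec, diameter,
                         orientation = spec$orientation,
                         spatial_frequency = spec$spatial_frequency,
                         phase = 0, contrast = 1, background = 0) {
  stopifnot(contrast >= 0, contrast <= 1)
  g <- background + grating_field(spec, orientation, spatial_frequency, phase, contrast)
  apply_circular_mask(spec, g, diameter, background)
}

#' Compound center-surround grating
#'
#' A central grating disc plus an annular surround grating with independent
#' orientation (matched or orthogonal to the center in the classic surround
#' experiments); the gap between the center aperture and the annulus inner
#' edge is mean gray.
#'
#' @inheritParams make_grating
#' @param center_diameter Center disc diameter, degrees.
#' @param surround_inner,surround_outer Annulus inner/outer diameters, degrees.
#' @param center_orientation,surround_orientation Stripe orientations, degrees.
#' @param center_contrast,surround_contrast Contrasts in \[0, 1\].
#' @export
make_compound_grating <- function(spec,
                                  center_diameter,
                                  surround_inner,
                                  surround_outer,
                                  center_orientation = spec$orientation,
                                  surround_orientation = spec$orientation,
                                  spatial_frequency = spec$spatial_frequency,
                                  phase = 0,
                                  center_contrast = 1,
                                  surround_contrast = 1,
                                  background = 0) {
  if (surround_inner < center_diameter)
    stop("surround annulus overlaps the center aperture (surround_inner < center_diameter)",
         call. = FALSE)
  if (surround_outer <= surround_inner)
    stop("surround_outer must exceed surround_inner", call. = FALSE)
  ctr <- make_grating(spec, center_diameter, center_orientation,
                      spatial_frequency, phase, center_contrast, background = 0)
  sur <- grating_field(spec, surround_orientation, spatial_frequency, phase,
                       surround_contrast)
  ann <- aperture_mask(spec, surround_outer) & !aperture_mask(spec, surround_inner)
  out <- matrix(background, spec$patch_size_px, spec$patch_size_px)
  cm <- aperture_mask(spec, center_diameter)
  out[cm] <- out[cm] + ctr[cm]
  out[ann] <- background + sur[ann]
  out
}

# One unnormalized 1/f-amplitude patch from white Gaussian noise.
pink_patch <- function(n) {
  z <- matrix(stats::rnorm(n * n), n, n)
  f1 <- c(0:(floor(n / 2)), -((ceiling(n / 2) - 1):1)) / n   # cycles/pixel
  fr <- sqrt(outer(f1^2, f1^2, `+`))
  amp <- ifelse(fr > 0, 1 / fr, 0)
  Re(stats::fft(stats::fft(z) * amp, inverse = TRUE)) / (n * n)
}

#' Seeded texture ensembles (white noise and 1/f surrogates)
#'
#' `white_noise` patches have i.i.d. Gaussian pixels; `pink_texture` patches
#' have a 1/f amplitude spectrum with random phases, the second-order surrogate
#' for natural image patches used throughout this package when no image
#' database is available. With `standardize = TRUE` the ensemble is scaled to
#' unit RMS luminance (computed over all pixels of all patches), so individual
#' patches retain natural contrast variability around a fixed overall scale.
#'
#' @param spec A [filterbank_spec()] fixing the patch geometry.
#' @param kind `"white_noise"` or `"pink_texture"`.
#' @param n Number of patches.
#' @param seed Integer seed; the same seed reproduces the ensemble exactly.
#' @param standardize Scale the ensemble to unit RMS luminance.
#' @return 3-D array (patch x patch x n) with attributes `kind` and `seed`.
#' @export
make_texture_ensemble <- function(spec, kind = c("pink_texture", "white_noise"),
                                  n, seed = NULL, standardize = TRUE) {
  kind <- match.arg(kind)
  stopifnot(n >= 1)
  px <- spec$patch_size_px
  out <- with_seed(seed, {
    if (kind == "white_noise") {
      array(pmin(pmax(stats::rnorm(px * px * n), -5), 5), dim = c(px, px, n))
    } else {
      a <- array(0, dim = c(px, px, n))
      for (i in seq_len(n)) a[, , i] <- pink_patch(px)
      a
    }
  })
  if (standardize) {
    rms <- sqrt(mean(out^2))
    if (rms > 0) out <- out / rms
  }
  attr(out, "kind") <- kind
  attr(out, "seed") <- seed
  out
}

read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop(sprintf("unsupported image format '%s' (PNG/TIFF supported)", ext),
                     call. = FALSE))
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:min(3, dim(img)[3]), drop = FALSE],
                                           c(1, 2), mean)
  img
}

#' Load grayscale patches from image files
#'
#' Reads PNG/TIFF images from a directory (or explicit file list), converts to
#' grayscale, rescales luminance to \[-1, 1\] around the image mean, and cuts
#' random patches in the bank's geometry. With
#' `selection = "rf_signal_above_median"`, `2n` candidate patches are drawn and
#' the n whose RF signal strength ([rf_signal_strength()]) is at or above the
#' candidate median are retained, mirroring the selection used for
#' natural-image ensembles.
#'
#' @param path Directory containing images, or a character vector of files.
#' @param n Number of patches to return.
#' @param spec A [filterbank_spec()].
#' @param seed Integer seed for patch positions.
#' @param selection `"random"` or `"rf_signal_above_median"`.
#' @param bank Filter bank (required for the signal-strength selection;
#'   built from `spec` if missing).
#' @return 3-D array of patches (patch x patch x n).
#' @export
load_image_patches <- function(path, n, spec, seed = NULL,
                               selection = c("random", "rf_signal_above_median"),
                               bank = NULL) {
  selection <- match.arg(selection)
  files <- if (length(path) == 1L && dir.exists(path))
    list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
               full.names = TRUE)
  else path[file.exists(path)]
  if (length(files) == 0L)
    stop("no readable PNG/TIFF images at ", paste(path, collapse = ", "),
         call. = FALSE)
  imgs <- lapply(files, read_gray_image)
  px <- spec$patch_size_px
  ok <- vapply(imgs, function(im) nrow(im) >= px && ncol(im) >= px, logical(1))
  if (!any(ok))
    stop(sprintf("no image is at least %d x %d pixels", px, px), call. = FALSE)
  imgs <- imgs[ok]
  imgs <- lapply(imgs, function(im) {
    im <- im - mean(im)
    mx <- max(abs(im))
    if (mx > 0) im / mx else im
  })
  n_cand <- if (selection == "rf_signal_above_median") 2L * n else n
  patches <- with_seed(seed, {
    a <- array(0, dim = c(px, px, n_cand))
    for (i in seq_len(n_cand)) {
      im <- imgs[[sample.int(length(imgs), 1L)]]
      r0 <- sample.int(nrow(im) - px + 1L, 1L)
      c0 <- sample.int(ncol(im) - px + 1L, 1L)
      a[, , i] <- im[r0:(r0 + px - 1L), c0:(c0 + px - 1L)]
    }
    a
  })
  if (selection == "rf_signal_above_median") {
    if (is.null(bank)) bank <- build_filterbank(spec)
    sig <- rf_signal_strength(apply_filterbank(bank, patches))
    keep <- order(sig, decreasing = TRUE)[seq_len(n)]
    patches <- patches[, , sort(keep), drop = FALSE]
  }
  if (dim(patches)[3] < n)
    stop(sprintf("requested %d patches but only %d available", n, dim(patches)[3]),
         call. = FALSE)
  patches
}
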