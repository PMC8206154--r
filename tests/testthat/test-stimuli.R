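# Stimulus generators: gratings, compound gratings, texture ensembles,
# image-patch loading.

spec <- filterbank_spec()

test_that("gratings respect contrast, phase symmetry, and the aperture", {
  expect_equal(make_grating(spec, 2, contrast = 0),
               matrix(0, 80, 80), tolerance = 1e-15)
  g0 <- make_grating(spec, 1.5, phase = 0)
  g180 <- make_grating(spec, 1.5, phase = 180)
  expect_equal(g180, -g0, tolerance = 1e-12)
  out <- !aperture_mask(spec, 1.5)
  expect_true(all(g0[out] == 0))
  expect_error(make_grating(spec, 4.5), "exceeds")
})

test_that("RF energy over the size series is maximal for the full-patch grating", {
  bank <- default_bank()
  sizes <- c(0.34, 0.55, 0.90, 2.4, 3.8)
  en <- vapply(sizes, function(d)
    rf_signal_strength(apply_filterbank(bank, make_grating(spec, d))),
    numeric(1))
  expect_true(all(diff(en) >= -1e-6 * max(en)))
  expect_gte(en[length(en)], 0.999 * max(en))
})

test_that("compound gratings compose center and annulus correctly", {
  ctr <- make_grating(spec, 0.9)
  cmp0 <- make_compound_grating(spec, 0.9, 1.1, 3.8, surround_contrast = 0)
  expect_equal(cmp0, ctr, tolerance = 1e-12)
  m <- make_compound_grating(spec, 0.9, 1.1, 3.8)
  o <- make_compound_grating(spec, 0.9, 1.1, 3.8,
                             surround_orientation = spec$orientation + 90)
  inside <- aperture_mask(spec, 0.9)
  expect_identical(m[inside], o[inside])
  gap <- aperture_mask(spec, 1.1) & !aperture_mask(spec, 0.9)
  expect_true(all(m[gap] == 0))
  expect_error(make_compound_grating(spec, 1.2, 1.1, 3.8), "overlaps")
})

test_that("matched surrounds drive the surround filters harder than orthogonal", {
  bank <- default_bank()
  xm <- apply_filterbank(bank, make_compound_grating(spec, 0.9, 1.1, 3.8))
  xo <- apply_filterbank(bank, make_compound_grating(spec, 0.9, 1.1, 3.8,
                                                     surround_orientation = 180))
  surround_energy <- function(x) sum(x[3:18]^2)
  expect_gt(surround_energy(xm), surround_energy(xo))
})

test_that("texture ensembles are seeded and have the right spectra", {
  a <- make_texture_ensemble(spec, "pink_texture", 8, seed = 5)
  b <- make_texture_ensemble(spec, "pink_texture", 8, seed = 5)
  expect_identical(a, b)
  radial_amplitude <- function(imgs) {
    n <- dim(imgs)[1]
    P <- 0
    for (i in seq_len(dim(imgs)[3]))
      P <- P + Mod(fft(imgs[, , i]))^2
    f1 <- c(0:(n / 2), -((n / 2 - 1):1)) / n
    fr <- sqrt(outer(f1^2, f1^2, `+`))
    bins <- cut(as.vector(fr), breaks = seq(0.02, 0.4, by = 0.02))
    amp <- sqrt(tapply(as.vector(P), bins, mean))
    f <- tapply(as.vector(fr), bins, mean)
    ok <- is.finite(amp) & amp > 0
    coef(lm(log(amp[ok]) ~ log(f[ok])))[2]
  }
  wn <- make_texture_ensemble(spec, "white_noise", 40, seed = 6)
  expect_lt(abs(radial_amplitude(wn)), 0.1)           # flat spectrum
  pk <- make_texture_ensemble(spec, "pink_texture", 40, seed = 7)
  expect_lt(abs(radial_amplitude(pk) - (-1)), 0.2)    # 1/f amplitude
  expect_equal(sqrt(mean(pk^2)), 1, tolerance = 1e-12) # ensemble RMS standardization
})

test_that("stimulus energy is non-decreasing in aperture diameter", {
  set.seed(8)
  base <- make_texture_ensemble(spec, "pink_texture", 1, seed = 8)[, , 1]
  en <- vapply(c(0.3, 0.6, 1, 2, 3, 4), function(d)
    sum(apply_circular_mask(spec, base, d)^2), numeric(1))
  expect_true(all(diff(en) >= 0))
})

test_that("image patches load, reproduce under a seed, and honor the median selection", {
  dir <- withr::local_tempdir()
  set.seed(3)
  big1 <- matrix(runif(200 * 200), 200)
  big2 <- outer(seq(0, 1, length.out = 200), seq(0, 1, length.out = 200))
  png::writePNG(big1, file.path(dir, "a.png"))
  tiff::writeTIFF(big2, file.path(dir, "b.tiff"))
  p1 <- load_image_patches(dir, 6, spec, seed = 10)
  p2 <- load_image_patches(dir, 6, spec, seed = 10)
  expect_identical(p1, p2)
  expect_equal(dim(p1), c(80, 80, 6))
  expect_true(all(abs(p1) <= 1))
  bank <- default_bank()
  sel <- load_image_patches(dir, 6, spec, seed = 11,
                            selection = "rf_signal_above_median", bank = bank)
  expect_equal(dim(sel)[3], 6L)
  cand <- load_image_patches(dir, 12, spec, seed = 11)
  sig_all <- rf_signal_strength(apply_filterbank(bank, cand))
  sig_sel <- rf_signal_strength(apply_filterbank(bank, sel))
  expect_true(all(sig_sel >= median(sig_all) - 1e-12))
  expect_error(load_image_patches(file.path(dir, "none"), 2, spec), "no readable")
})
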