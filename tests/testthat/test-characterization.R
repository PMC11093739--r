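test_that("Gaussian profile fits recover exact parameters on clean data", {
  xs <- seq(-10, 10, by = 0.25)
  ys <- 10 + 100 * exp(-(xs - 0)^2 / (2 * 2^2))
  f <- fit_gaussian(xs, ys)
  expect_equal(f$a, 10, tolerance = 1e-6)
  expect_equal(f$b, 100, tolerance = 1e-6)
  expect_equal(f$mu, 0, tolerance = 1e-6)
  expect_equal(f$sigma, 2, tolerance = 1e-6)
  expect_lt(f$rss, 1e-10)

  expect_error(fit_gaussian(xs, rep(5, length(xs))), "constant")
  expect_error(fit_gaussian(1:4, c(1, 2, 3, 2)), "at least 5")
})

test_that("noisy fits recover sigma within a few percent (SNR 20)", {
  xs <- seq(-10, 10, by = 0.25)
  clean <- 10 + 100 * exp(-xs^2 / (2 * 2^2))
  errs <- vapply(1:50, function(seed) {
    ys <- duofuse:::with_seed(seed, clean + rnorm(length(xs), 0, 100 / 20))
    abs(fit_gaussian(xs, ys)$sigma - 2) / 2
  }, numeric(1))
  expect_lt(median(errs), 0.03)
})

test_that("FWHM and beam-waist conversions follow the Gaussian closed forms", {
  expect_equal(fwhm_from_sigma(1), 2 * sqrt(2 * log(2)))
  expect_equal(fwhm_from_sigma(2), 2 * fwhm_from_sigma(1))
  expect_error(fwhm_from_sigma(0), "positive")
  ## constant ratio across scales
  sig <- c(0.1, 0.34, 1.23, 7)
  expect_equal(fwhm_from_sigma(sig) / sig, rep(2 * sqrt(2 * log(2)), 4))

  expect_equal(beam_waist_from_sigma(1), 2)
  expect_error(beam_waist_from_sigma(-1), "positive")
  ## 1/e^2 round trip: intensity exp(-2 x^2 / w0^2) with w0 = 3
  xs <- seq(-8, 8, by = 0.1)
  f <- fit_gaussian(xs, exp(-2 * xs^2 / 9))
  expect_equal(beam_waist_from_sigma(f$sigma), 3, tolerance = 1e-6)
})

test_that("effective NA and Rayleigh length follow Gaussian-beam optics", {
  expect_equal(effective_na(1.33, 0.488, 3.443), 0.060, tolerance = 1e-3)
  w0 <- 2.5
  expect_equal(effective_na(1.33, 0.488, 2 * w0),
               effective_na(1.33, 0.488, w0) / 2)
  expect_error(effective_na(1.33, 0, 3), "positive")

  expect_equal(rayleigh_length(1, 1, pi), 1)
  expect_equal(rayleigh_length(2, 1.33, 0.488),
               4 * rayleigh_length(1, 1.33, 0.488))
  ## width-vs-z fit route recovers z_r from a simulated beam caustic
  w0 <- 3; zr_true <- rayleigh_length(w0, 1.33, 0.488)
  zs <- seq(-150, 150, by = 5)
  ws <- w0 * sqrt(1 + (zs / zr_true)^2)
  fit <- fit_beam_widths(zs, ws)
  expect_equal(fit$zr, zr_true, tolerance = 0.02)
  expect_equal(fit$w0, w0, tolerance = 0.02)
})

test_that("scaling the profile width scales NA_eff inversely", {
  for (k in c(0.5, 2, 3)) {
    na1 <- effective_na(1.33, 0.488, beam_waist_from_sigma(1.5))
    nak <- effective_na(1.33, 0.488, beam_waist_from_sigma(1.5 / k))
    expect_equal(nak / na1, k, tolerance = 1e-12)
  }
})

test_that("bead-field PSF measurement recovers the generator FWHM", {
  bp <- bead_phantom(shape = c(48, 128, 128), n_beads = 12,
                     psf_sigma = c(0.34, 1.23), seed = 21)
  m <- measure_psf(bp, threshold = 200)
  expect_gt(m$n_beads, 5)
  expect_equal(m$fwhm_lateral, fwhm_from_sigma(0.34), tolerance = 0.02)
  expect_equal(m$fwhm_axial, fwhm_from_sigma(1.23), tolerance = 0.02)
  expect_gte(m$fwhm_axial, m$fwhm_lateral)

  ## Poisson noise at peak SNR ~30: still within 5% over seeds
  errs <- vapply(1:3, function(s) {
    noisy <- add_poisson_noise(bp, peak = 900, seed = s)
    mm <- measure_psf(noisy, threshold = 200)
    max(abs(mm$fwhm_lateral / fwhm_from_sigma(0.34) - 1),
        abs(mm$fwhm_axial / fwhm_from_sigma(1.23) - 1))
  }, numeric(1))
  expect_lt(max(errs), 0.05)

  expect_error(measure_psf(volume_stack(array(0, c(20, 20, 20))), 100),
               "no beads")
})

test_that("field of view is pixel count times pixel spacing", {
  expect_equal(field_of_view(2304, 0.406), 2304 * 0.406, tolerance = 1e-12)
  expect_lte(abs(field_of_view(2304, 0.406) - 935), 0.5)  # printed side
  expect_equal(field_of_view(1, 0.65), 0.65)
  expect_error(field_of_view(0, 0.406), "positive")
})

test_that("characterize_beam chains fit and conversions consistently", {
  xs <- seq(-12, 12, by = 0.2)
  sigma <- 1.7215  # w0 = 3.443 um
  ys <- 50 + 800 * exp(-xs^2 / (2 * sigma^2))
  bm <- characterize_beam(xs, ys, n = 1.33, lambda = 0.488)
  expect_equal(bm$w0, 2 * sigma, tolerance = 1e-6)
  expect_equal(bm$na_eff, 0.060, tolerance = 1e-3)
  expect_equal(bm$fwhm, fwhm_from_sigma(sigma), tolerance = 1e-6)
  expect_equal(bm$zr, rayleigh_length(2 * sigma, 1.33, 0.488),
               tolerance = 1e-6)
})
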