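#' Fit a Gaussian with constant offset to a line profile
#'
#' Least-squares fit of `f(x) = a + b * exp(-(x - mu)^2 / (2 sigma^2))`,
#' the model used for static light-sheet beam profiles and bead intensity
#' profiles. Initialization from moments: `a` from the minimum, `b` from the
#' range, `mu` from the argmax, `sigma` from the second moment of the
#' offset-subtracted profile. Levenberg-Marquardt refinement.
#'
#' @param xs sample positions (micrometres), at least 5.
#' @param ys intensities (counts); must not be constant.
#' @return A `GaussianFit`: list with `a`, `b`, `mu`, `sigma` (> 0), `rss`
#'   and the `fitted` values.
#' @examples
#' xs <- seq(-10, 10, 0.25)
#' f <- fit_gaussian(xs, 10 + 100 * exp(-xs^2 / 8))
#' c(f$mu, f$sigma)
#' @export
fit_gaussian <- function(xs, ys) {
  xs <- as.numeric(xs); ys <- as.numeric(ys)
  if (length(xs) != length(ys)) stopf("xs and ys must have equal length")
  if (length(xs) < 5L) stopf("need at least 5 samples to fit a Gaussian")
  if (!all(is.finite(xs)) || !all(is.finite(ys)))
    stopf("xs and ys must be finite")
  if (sd(ys) == 0) stopf("degenerate fit: ys is constant")
  a0 <- min(ys)
  b0 <- max(ys) - a0
  mu0 <- xs[which.max(ys)]
  w <- pmax(ys - a0, 0)
  s0 <- sqrt(sum(w * (xs - mu0)^2) / sum(w))
  if (!is.finite(s0) || s0 <= 0) s0 <- diff(range(xs)) / 4
  ## analytic gradient: numeric differentiation breaks down when a
  ## converged parameter (typically mu) is within rounding of zero
  model <- deriv(~ a + b * exp(-(x - mu)^2 / (2 * sigma^2)),
                 c("a", "b", "mu", "sigma"),
                 function.arg = c("x", "a", "b", "mu", "sigma"))
  fit <- tryCatch(
    nlsLM(y ~ model(x, a, b, mu, sigma),
          data = data.frame(x = xs, y = ys),
          start = list(a = a0, b = b0, mu = mu0, sigma = s0),
          control = nls.lm.control(maxiter = 200, ftol = 1e-12,
                                   ptol = 1e-12)),
    error = function(e) stopf("Gaussian fit did not converge: %s",
                              conditionMessage(e)))
  p <- coef(fit)
  if (!is.finite(p[["sigma"]]) || p[["sigma"]] == 0)
    stopf("Gaussian fit did not converge (sigma = %g)", p[["sigma"]])
  structure(list(a = p[["a"]], b = p[["b"]], mu = p[["mu"]],
                 sigma = abs(p[["sigma"]]), rss = sum(resid(fit)^2),
                 fitted = as.numeric(stats::fitted(fit))),
            class = "GaussianFit")
}

#' @export
print.GaussianFit <- function(x, ...) {
  cat(sprintf("GaussianFit: a = %.6g, b = %.6g, mu = %.6g, sigma = %.6g (rss %.3g)\n",
              x$a, x$b, x$mu, x$sigma, x$rss))
  invisible(x)
}

#' Full width at half maximum of a Gaussian profile
#'
#' `FWHM = 2 sqrt(2 ln 2) sigma` (about `2.3548 sigma`).
#'
#' @param sigma Gaussian standard deviation in micrometres (> 0).
#' @return FWHM in micrometres.
#' @export
fwhm_from_sigma <- function(sigma) {
  check_positive(sigma, "sigma")
  2 * sqrt(2 * log(2)) * sigma
}

#' Beam waist from the fitted intensity-profile width
#'
#' The 1/e^2 intensity radius of a Gaussian beam whose transverse intensity
#' profile has standard deviation `sigma` is `w0 = 2 sigma`.
#'
#' @param sigma standard deviation of the fitted intensity profile (um).
#' @return Beam waist `w0` in micrometres.
#' @export
beam_waist_from_sigma <- function(sigma) {
  check_positive(sigma, "sigma")
  2 * sigma
}

#' Effective numerical aperture from the beam waist
#'
#' `NA_eff = n * lambda / (pi * w0)`: the aperture actually filled by the
#' illumination beam, typically well below the objective's nominal NA.
#'
#' @param n refractive index of the immersion medium.
#' @param lambda wavelength in micrometres.
#' @param w0 beam waist in micrometres.
#' @return Dimensionless effective NA.
#' @examples
#' effective_na(1.33, 0.488, 3.443)  # ~0.06
#' @export
effective_na <- function(n, lambda, w0) {
  check_positive(c(n, lambda, w0), "n, lambda, w0")
  n * lambda / (pi * w0)
}

#' Rayleigh length of a Gaussian beam
#'
#' `z_r = pi * w0^2 * n / lambda`: the propagation distance over which the
#' beam area doubles (width grows by sqrt(2)).
#'
#' @inheritParams effective_na
#' @return Rayleigh length in micrometres.
#' @export
rayleigh_length <- function(w0, n, lambda) {
  check_positive(c(w0, n, lambda), "w0, n, lambda")
  pi * w0^2 * n / lambda
}

#' Fit the axial width profile of a Gaussian beam
#'
#' Alternative, fit-based route to `w0` and `z_r`: given per-z beam widths
#' `w(z)`, fits `w(z) = w0 sqrt(1 + ((z - z0) / zr)^2)`.
#'
#' @param zs axial positions (um).
#' @param ws beam 1/e^2 radii at each position (um).
#' @return List with `w0`, `z0`, `zr` (all um) and `rss`.
#' @export
fit_beam_widths <- function(zs, ws) {
  zs <- as.numeric(zs); ws <- as.numeric(ws)
  if (length(zs) < 5L) stopf("need at least 5 width samples")
  if (any(ws <= 0)) stopf("beam widths must be positive")
  i0 <- which.min(ws)
  model <- deriv(~ w0 * sqrt(1 + ((z - z0) / zr)^2), c("w0", "z0", "zr"),
                 function.arg = c("z", "w0", "z0", "zr"))
  fit <- tryCatch(
    nlsLM(w ~ model(z, w0, z0, zr),
          data = data.frame(z = zs, w = ws),
          start = list(w0 = ws[i0], z0 = zs[i0], zr = diff(range(zs)) / 4),
          control = nls.lm.control(maxiter = 200, ftol = 1e-12)),
    error = function(e) stopf("beam width fit did not converge: %s",
                              conditionMessage(e)))
  p <- coef(fit)
  list(w0 = abs(p[["w0"]]), z0 = p[["z0"]], zr = abs(p[["zr"]]),
       rss = sum(resid(fit)^2))
}

#' Field-of-view side length from the camera geometry
#'
#' @param n_pixels sensor pixels along one side.
#' @param pixel_spacing projected pixel size in micrometres.
#' @return Side length in micrometres.
#' @examples
#' field_of_view(2304, 0.406)  # 935.4 um
#' @export
field_of_view <- function(n_pixels, pixel_spacing) {
  check_positive(c(n_pixels, pixel_spacing), "n_pixels, pixel_spacing")
  n_pixels * pixel_spacing
}

## Local maxima of a 3D array above `threshold`: candidate voxels that are
## >= all 26 neighbours (strictly > at least one to break plateaus is not
## required; duplicate plateau peaks are merged by the exclusion radius).
local_maxima_3d <- function(a, threshold) {
  d <- dim(a)
  cand <- which(a > threshold, arr.ind = TRUE)
  if (!nrow(cand)) return(cand)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    z <- cand[i, 1]; y <- cand[i, 2]; x <- cand[i, 3]
    nb <- a[max(1, z - 1):min(d[1], z + 1),
            max(1, y - 1):min(d[2], y + 1),
            max(1, x - 1):min(d[3], x + 1)]
    keep[i] <- a[z, y, x] >= max(nb)
  }
  cand[keep, , drop = FALSE]
}

#' Measure the point spread function from a bead-field stack
#'
#' Detects isolated sub-resolution beads as local intensity maxima above a
#' threshold, extracts line profiles through each peak along x (lateral)
#' and z (axial), fits each with [fit_gaussian()], converts the fitted
#' widths with [fwhm_from_sigma()] and averages over beads. Beads whose
#' profile window is clipped by the stack border are discarded; pairs of
#' maxima closer than the exclusion radius are dropped (count reported).
#'
#' @param stack a [volume_stack()] of a bead field.
#' @param threshold detection threshold in counts.
#' @param exclusion_radius_vox minimum peak separation in voxels; closer
#'   pairs are removed as overlapping beads.
#' @param window_lateral_um,window_axial_um half-width of the fitted
#'   profile along x and z, in micrometres.
#' @return A `PSFMeasurement`: list with `fwhm_lateral`, `fwhm_axial` (um,
#'   bead averages), `n_beads`, `depth` (mean bead z in um), `n_excluded`,
#'   and `beads` (per-bead data.frame: z, y, x in um, fwhm_xy, fwhm_xz).
#' @export
measure_psf <- function(stack, threshold, exclusion_radius_vox = 3,
                        window_lateral_um = 2.5, window_axial_um = 6) {
  stack <- as_volume(stack)
  a <- stack$data
  sp <- stack$spacing
  pk <- local_maxima_3d(a, threshold)
  if (!nrow(pk)) stopf("no beads detected above threshold %g", threshold)

  ## drop overlapping peaks (any pair within the exclusion radius)
  n_excluded <- 0L
  if (nrow(pk) > 1L) {
    phys <- sweep(pk - 1, 2, sp, `*`)
    dd <- as.matrix(dist(phys)) / mean(sp)
    bad <- apply(dd + diag(Inf, nrow(dd)), 1, min) < exclusion_radius_vox
    n_excluded <- sum(bad)
    pk <- pk[!bad, , drop = FALSE]
  }
  if (!nrow(pk))
    stopf("no isolated beads left after removing overlapping pairs")

  d <- dim(a)
  hx <- ceiling(window_lateral_um / sp[3])
  hz <- ceiling(window_axial_um / sp[1])
  rows <- list()
  for (i in seq_len(nrow(pk))) {
    z <- pk[i, 1]; y <- pk[i, 2]; x <- pk[i, 3]
    if (x - hx < 1 || x + hx > d[3] || z - hz < 1 || z + hz > d[1])
      next  # clipped by the border
    prof_x <- a[z, y, (x - hx):(x + hx)]
    prof_z <- a[(z - hz):(z + hz), y, x]
    fx <- tryCatch(fit_gaussian(((x - hx):(x + hx) - 1) * sp[3], prof_x),
                   error = function(e) NULL)
    fz <- tryCatch(fit_gaussian(((z - hz):(z + hz) - 1) * sp[1], prof_z),
                   error = function(e) NULL)
    if (is.null(fx) || is.null(fz)) next
    rows[[length(rows) + 1L]] <- data.frame(
      z = (z - 1) * sp[1], y = (y - 1) * sp[2], x = (x - 1) * sp[3],
      fwhm_xy = fwhm_from_sigma(fx$sigma),
      fwhm_xz = fwhm_from_sigma(fz$sigma))
  }
  if (!length(rows))
    stopf("no beads could be fitted (all clipped or degenerate)")
  beads <- do.call(rbind, rows)
  structure(list(fwhm_lateral = mean(beads$fwhm_xy),
                 fwhm_axial = mean(beads$fwhm_xz),
                 n_beads = nrow(beads), depth = mean(beads$z),
                 n_excluded = n_excluded, beads = beads),
            class = "PSFMeasurement")
}

#' @export
print.PSFMeasurement <- function(x, ...) {
  cat(sprintf("PSFMeasurement: FWHM %.3f um lateral / %.3f um axial (%d beads, %d excluded)\n",
              x$fwhm_lateral, x$fwhm_axial, x$n_beads, x$n_excluded))
  invisible(x)
}

#' Characterize a light-sheet beam profile
#'
#' Convenience wrapper: fit the transverse intensity profile, convert to
#' FWHM, beam waist, effective NA and Rayleigh length.
#'
#' @param xs,ys transverse profile positions (um) and intensities.
#' @param n refractive index (water: 1.33).
#' @param lambda wavelength in micrometres.
#' @return A `BeamMeasurement`: list with the `GaussianFit`, `fwhm`, `w0`,
#'   `na_eff`, `zr`, `n`, `lambda`.
#' @export
characterize_beam <- function(xs, ys, n = 1.33, lambda = 0.488) {
  fit <- fit_gaussian(xs, ys)
  w0 <- beam_waist_from_sigma(fit$sigma)
  structure(list(fit = fit, fwhm = fwhm_from_sigma(fit$sigma), w0 = w0,
                 na_eff = effective_na(n, lambda, w0),
                 zr = rayleigh_length(w0, n, lambda),
                 n = n, lambda = lambda),
            class = "BeamMeasurement")
}

#' @export
print.BeamMeasurement <- function(x, ...) {
  cat(sprintf("BeamMeasurement: w0 = %.3f um, FWHM = %.3f um, NA_eff = %.4f, z_r = %.1f um\n",
              x$w0, x$fwhm, x$na_eff, x$zr))
  invisible(x)
}
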