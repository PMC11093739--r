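#' Depth-dependent degradation model for synthetic dual-view pairs
#'
#' Emulates what each detection objective sees through a thick specimen:
#' Gaussian blur growing linearly with distance from the view's near
#' surface (`sigma(z) = blur_sigma0 + blur_rate * z` voxels), exponential
#' intensity attenuation with depth, an optional Poisson noise stage
#' applied after blur and attenuation (camera-physics order), and a
#' constant camera background offset per view added last.
#'
#' @param blur_sigma0 blur at the near surface, in voxels.
#' @param blur_rate blur growth per plane, voxels/plane.
#' @param attenuation_rate exponential decay per micrometre of depth.
#' @param poisson_peak if non-NULL, intensities are Poisson-sampled (counts).
#' @param background camera offsets in counts, length 2 `(view1, view2)`.
#' @return A `DegradationModel` list.
#' @export
degradation_model <- function(blur_sigma0 = 0.5, blur_rate = 0.1,
                              attenuation_rate = 0.01, poisson_peak = NULL,
                              background = c(100, 100)) {
  if (blur_sigma0 < 0 || blur_rate < 0 || attenuation_rate < 0)
    stopf("blur and attenuation parameters must be >= 0")
  if (any(background < 0)) stopf("background offsets must be >= 0")
  if (length(background) == 1L) background <- rep(background, 2L)
  structure(list(blur_sigma0 = blur_sigma0, blur_rate = blur_rate,
                 attenuation_rate = attenuation_rate,
                 poisson_peak = poisson_peak,
                 background = background), class = "DegradationModel")
}

blur_plane <- function(plane, sigma) {
  if (sigma < 0.05) return(plane)
  ## cap the kernel so it never exceeds the plane (strong blur, small plane)
  r <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  rmax <- min(dim(plane))
  if (rmax %% 2L == 0L) rmax <- rmax - 1L
  as.matrix(gblur(plane, sigma = sigma, radius = min(r, rmax),
                  boundary = "replicate"))
}

## Degrade a truth stack as one view sees it: per-plane blur width given by
## `sigmas` (voxels), per-plane attenuation factors `atten`.
degrade_stack <- function(truth, sigmas, atten) {
  out <- truth
  ## clamp: FFT-based filtering can leave values a few ulp below zero
  for (z in seq_along(sigmas))
    out[z, , ] <- pmax(blur_plane(truth[z, , ], sigmas[z]), 0) * atten[z]
  out
}

#' Synthetic dual-view stack pair with known ground truth
#'
#' Degrades a truth stack twice: view 1 blurs and attenuates increasingly
#' toward high z, view 2 toward low z. The blur rates are chosen so the two
#' blur widths are equal exactly at `crossover`, which is returned as the
#' ground-truth switching plane. View 2 is additionally displaced by
#' `misalignment`, mirrored along z (as the opposing camera records it) and
#' offset by its own background.
#'
#' @param truth a [volume_stack()] of noise-free structure.
#' @param model a [degradation_model()].
#' @param misalignment a [rigid_transform()]; identity by default.
#' @param crossover ground-truth crossover plane (0-based, defaults to the
#'   stack middle `(nz - 1) / 2`).
#' @param seed RNG seed for the Poisson stage (only used when the model has
#'   `poisson_peak`).
#' @return List with `view1`, `view2` (VolumeStacks as recorded),
#'   `crossover`, `misalignment`, and `view2_aligned` (view 2's degraded
#'   stack before misalignment/flip, for oracle use).
#' @export
dual_view_pair <- function(truth, model = degradation_model(),
                           misalignment = rigid_transform(),
                           crossover = NULL, seed = NULL) {
  truth <- as_volume(truth, "truth")
  if (!inherits(model, "DegradationModel"))
    stopf("'model' must be a degradation_model()")
  a <- truth$data
  nz <- dim(a)[1]
  cz <- crossover %||% ((nz - 1) / 2)
  if (cz <= 0 || cz >= nz - 1)
    stopf("crossover must lie strictly inside (0, nz - 1)")
  z <- 0:(nz - 1)
  k1 <- model$blur_rate
  k2 <- k1 * cz / (nz - 1 - cz)
  sig1 <- model$blur_sigma0 + k1 * z
  sig2 <- model$blur_sigma0 + k2 * (nz - 1 - z)
  dz <- truth$spacing[1]
  at1 <- exp(-model$attenuation_rate * z * dz)
  at2 <- exp(-model$attenuation_rate * (nz - 1 - z) * dz)

  d1 <- degrade_stack(a, sig1, at1)
  d2 <- degrade_stack(a, sig2, at2)

  identity_tr <- all(misalignment$rotation == 0) &&
    all(misalignment$translation == 0)
  v2m <- if (identity_tr) d2 else
    resample(volume_stack(d2, truth$spacing),
             invert_transform(misalignment), background = 0)$data

  with_seed(seed, {
    if (!is.null(model$poisson_peak)) {
      scale1 <- model$poisson_peak / max(d1)
      d1 <- rpois(length(d1), d1 * scale1) / scale1
      dim(d1) <- dim(a)
      scale2 <- model$poisson_peak / max(v2m)
      v2m <- rpois(length(v2m), v2m * scale2) / scale2
      dim(v2m) <- dim(a)
    }
  })

  view1 <- volume_stack(d1 + model$background[1], truth$spacing, "view1")
  view2 <- volume_stack(v2m + model$background[2], truth$spacing, "view2")
  view2 <- flip_opposing_view(view2, "z")
  list(view1 = view1, view2 = view2, crossover = cz,
       misalignment = misalignment,
       view2_aligned = volume_stack(d2 + model$background[2], truth$spacing,
                                    "view2"))
}

#' Structured truth stack for fusion phantoms
#'
#' A seeded field of small bright blobs on a dark background - enough
#' texture at every depth for both the focus metric and the registration
#' metric to engage.
#'
#' @param shape voxel dimensions `(z, y, x)`.
#' @param n_blobs number of Gaussian blobs.
#' @param intensity peak blob intensity in counts.
#' @param sigma_vox isotropic blob width in voxels.
#' @param spacing micrometres per voxel.
#' @param seed RNG seed.
#' @return A `VolumeStack`.
#' @export
blob_phantom <- function(shape = c(50, 128, 128), n_blobs = 120,
                         intensity = 5000, sigma_vox = 1.2,
                         spacing = c(1, 1, 1), seed = NULL) {
  a <- array(0, shape)
  with_seed(seed, {
    pos <- cbind(runif(n_blobs, 2, shape[1] - 1),
                 runif(n_blobs, 2, shape[2] - 1),
                 runif(n_blobs, 2, shape[3] - 1))
    amp <- runif(n_blobs, 0.3, 1) * intensity
    for (i in seq_len(n_blobs))
      a <- add_gaussian_spot(a, pos[i, ], c(sigma_vox, sigma_vox, sigma_vox),
                             amp[i])
  })
  volume_stack(a, spacing)
}

## Add one anisotropic Gaussian spot (sigmas in voxels, pos 0-based voxel
## coordinates, separable rendering on a local box of +-5 sigma).
add_gaussian_spot <- function(a, pos, sigma_vox, amplitude) {
  d <- dim(a)
  rng <- lapply(1:3, function(ax) {
    lo <- max(0, floor(pos[ax] - 5 * sigma_vox[ax]))
    hi <- min(d[ax] - 1, ceiling(pos[ax] + 5 * sigma_vox[ax]))
    lo:hi
  })
  g <- lapply(1:3, function(ax)
    exp(-(rng[[ax]] - pos[ax])^2 / (2 * sigma_vox[ax]^2)))
  spot <- amplitude * (g[[1]] %o% g[[2]] %o% g[[3]])
  a[rng[[1]] + 1, rng[[2]] + 1, rng[[3]] + 1] <-
    a[rng[[1]] + 1, rng[[2]] + 1, rng[[3]] + 1] + spot
  a
}

#' Bead-field phantom with known PSF
#'
#' Places beads at uniform random sub-voxel positions (with a margin of 5
#' sigma from every border and a minimum pairwise separation) and renders
#' each as an anisotropic Gaussian of unit peak - the image a diffraction-
#' limited microscope with Gaussian PSF takes of point-like beads.
#'
#' @param shape voxel dimensions `(z, y, x)`.
#' @param n_beads number of beads.
#' @param psf_sigma `(lateral, axial)` Gaussian PSF widths in micrometres.
#' @param spacing micrometres per voxel along `(z, y, x)`.
#' @param peak bead peak intensity in counts.
#' @param min_separation_um minimum pairwise bead distance; placement fails
#'   with an overcrowding error after `max_retries` rejected draws.
#' @param max_retries placement retry budget.
#' @param seed RNG seed (same seed, same stack).
#' @return A `VolumeStack`; attribute `bead_positions` holds the ground
#'   truth data.frame (z, y, x in um).
#' @export
bead_phantom <- function(shape = c(60, 192, 192), n_beads = 30,
                         psf_sigma = c(0.34, 1.23),
                         spacing = c(0.406, 0.406, 0.406), peak = 1000,
                         min_separation_um = 10, max_retries = 5000,
                         seed = NULL) {
  check_positive(psf_sigma, "psf_sigma")
  ext <- (shape - 1) * spacing
  margin <- 5 * c(psf_sigma[2], psf_sigma[1], psf_sigma[1])  # (z, y, x) um
  if (any(ext - 2 * margin <= 0))
    stopf("stack too small for beads with a 5 sigma margin")
  a <- array(0, shape)
  pos <- matrix(numeric(0), 0, 3)
  with_seed(seed, {
    tries <- 0L
    while (nrow(pos) < n_beads) {
      p <- margin + runif(3) * (ext - 2 * margin)
      if (!nrow(pos) ||
          min(sqrt(colSums((t(pos) - p)^2))) >= min_separation_um) {
        pos <- rbind(pos, p)
      } else {
        tries <- tries + 1L
        if (tries > max_retries)
          stopf("bead placement overcrowded: %d of %d placed after %d retries",
                nrow(pos), n_beads, max_retries)
      }
    }
  })
  sig_vox <- c(psf_sigma[2] / spacing[1], psf_sigma[1] / spacing[2],
               psf_sigma[1] / spacing[3])
  for (i in seq_len(nrow(pos)))
    a <- add_gaussian_spot(a, pos[i, ] / spacing, sig_vox, peak)
  out <- volume_stack(a, spacing)
  if (nrow(pos)) {
    gt <- data.frame(z = pos[, 1], y = pos[, 2], x = pos[, 3])
  } else {
    gt <- data.frame(z = numeric(), y = numeric(), x = numeric())
  }
  attr(out, "bead_positions") <- gt
  out
}

#' Simulate ballistic or Brownian 3D cell tracks
#'
#' Ballistic: `r_i(t) = r_i(0) + v t` along a per-track random unit
#' direction, so the ensemble MSD is exactly `v^2 t^2`. Brownian:
#' independent Gaussian increments per axis with variance `2 D dt`, so the
#' expected MSD is `6 D t`. Starting positions are scattered uniformly in a
#' 100 um box. Deterministic per seed.
#'
#' @param kind `"ballistic"` or `"brownian"`.
#' @param n_tracks number of tracks.
#' @param n_steps steps per track (track length is `n_steps + 1` spots).
#' @param dt frame interval in hours.
#' @param v ballistic speed, um/h.
#' @param D diffusion coefficient, um^2/h.
#' @param seed RNG seed.
#' @return A [track_set()].
#' @export
simulate_tracks <- function(kind = c("brownian", "ballistic"), n_tracks = 50,
                            n_steps = 30, dt = 1 / 6, v = 5, D = 1,
                            seed = NULL) {
  kind <- match.arg(kind)
  check_positive(dt, "dt")
  if (kind == "ballistic") check_positive(v, "v") else check_positive(D, "D")
  with_seed(seed, {
    rows <- lapply(seq_len(n_tracks), function(i) {
      r0 <- runif(3, 0, 100)
      tt <- (0:n_steps) * dt
      if (kind == "ballistic") {
        u <- rnorm(3)
        u <- u / sqrt(sum(u^2))
        xyz <- cbind(r0[1] + v * tt * u[1], r0[2] + v * tt * u[2],
                     r0[3] + v * tt * u[3])
      } else {
        stepsd <- sqrt(2 * D * dt)
        xyz <- cbind(r0[1] + cumsum(c(0, rnorm(n_steps, 0, stepsd))),
                     r0[2] + cumsum(c(0, rnorm(n_steps, 0, stepsd))),
                     r0[3] + cumsum(c(0, rnorm(n_steps, 0, stepsd))))
      }
      data.frame(track = sprintf("t%04d", i), frame = 0:n_steps,
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    })
    track_set(do.call(rbind, rows), dt)
  })
}

#' Voxelized non-overlapping ellipsoid label phantom
#'
#' Each ellipsoid becomes one label by the implicit-equation test at voxel
#' centres; overlapping ellipsoids are a generation error.
#'
#' @param shape voxel dimensions `(z, y, x)`.
#' @param centers list of micrometre centre triples `(z, y, x)`.
#' @param semi_axes list of micrometre semi-axis triples `(z, y, x)`.
#' @param spacing micrometres per voxel.
#' @return A [label_volume()]; an empty `centers` list gives all zeros.
#' @export
ellipsoid_labels <- function(shape, centers, semi_axes,
                             spacing = c(1, 1, 1)) {
  if (length(centers) != length(semi_axes))
    stopf("centers and semi_axes must have the same length")
  a <- array(0L, shape)
  if (!length(centers)) return(label_volume(a, spacing))
  zc <- (seq_len(shape[1]) - 1) * spacing[1]
  yc <- (seq_len(shape[2]) - 1) * spacing[2]
  xc <- (seq_len(shape[3]) - 1) * spacing[3]
  for (i in seq_along(centers)) {
    ctr <- as.numeric(centers[[i]]); ax <- as.numeric(semi_axes[[i]])
    check_positive(ax, "semi_axes")
    qz <- ((zc - ctr[1]) / ax[1])^2
    qy <- ((yc - ctr[2]) / ax[2])^2
    qx <- ((xc - ctr[3]) / ax[3])^2
    inside <- outer(outer(qz, qy, `+`), qx, `+`) <= 1
    if (any(a[inside] != 0L))
      stopf("ellipsoid %d overlaps an earlier one", i)
    a[inside] <- i
  }
  label_volume(a, spacing)
}

#' Add Poisson camera noise to a stack
#'
#' Rescales so the stack maximum maps to `peak` expected counts, samples
#' each voxel from a Poisson law and scales back; the peak SNR is
#' `sqrt(peak)`.
#'
#' @param stack a [volume_stack()].
#' @param peak expected counts at the stack maximum.
#' @param seed RNG seed.
#' @return The noisy `VolumeStack`.
#' @export
add_poisson_noise <- function(stack, peak, seed = NULL) {
  stack <- as_volume(stack)
  check_positive(peak, "peak")
  m <- max(stack$data)
  if (m <= 0) return(stack)
  s <- peak / m
  with_seed(seed, {
    noisy <- rpois(length(stack$data), pmax(stack$data, 0) * s) / s
  })
  out <- stack
  out$data <- array(noisy, dim(stack$data))
  out
}
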