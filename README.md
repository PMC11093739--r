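# duofuse

Processing and quantification toolkit for **open-top dual-view light-sheet
microscopy**. Two detection objectives image the same specimen from opposing
sides along the optical axis; each view is sharp near its own objective and
degrades with depth, in opposite directions. `duofuse` turns the two raw
stacks into one uniformly sharp volume and provides the quantitative
machinery around it:

* **Dual-view fusion** — mirror the opposing view, correct the mechanical
  misalignment with a 6-DoF rigid registration
  (`T(p) = R (p - c) + c + t`, normalized cross-correlation or mutual
  information, deterministic multi-resolution Nelder-Mead), score every
  plane of both views with the **DCT Shannon-entropy focus metric**
  (`H = -sum p_k ln p_k` over the power-normalized 2D DCT spectrum), place
  the **switching plane** where the opposing view becomes sharper, and
  blend with sigmoidal weights
  `w2(z) = 1 / (1 + exp(-(z - z_switch)/s))`, subtracting the constant
  camera offset.
* **Optical characterization** — Gaussian line-profile fits
  `f(x) = a + b exp(-(x-mu)^2 / (2 sigma^2))`,
  `FWHM = 2 sigma sqrt(2 ln 2)`, beam waist `w0 = 2 sigma`, effective
  numerical aperture `NA_eff = n lambda / (pi w0)`, Rayleigh length
  `z_r = pi w0^2 n / lambda`, bead-field PSF measurement, and camera
  field-of-view arithmetic.
* **Single-cell motion statistics** — origin-anchored 3D mean square
  displacement `msd(t) = (1/N) sum_i (r_i(t) - r_i(0))^2`, per-step and
  per-track speeds, path lengths; reads Mastodon-style CSV track exports.
* **3D shape features** — IoU-based stitching of per-plane 2D label masks
  into 3D labels, moment-tensor major/minor axis lengths and ratios,
  volume/axis filtering of false segmentations.
* **Synthetic data** — seeded generators for dual-view pairs with known
  quality crossover and misalignment, bead phantoms with known PSF,
  ballistic/Brownian tracks, and ellipsoid label phantoms; every analysis
  above is testable against ground truth without any external data.

See `vignettes/duofuse-methods.Rmd` for the models, parameter choices and
limitations.

## Worked example

```r
library(duofuse)

## a synthetic specimen and the two views a dual-view microscope records,
## with depth-dependent blur/attenuation crossing over at plane 30
truth <- blob_phantom(shape = c(50, 128, 128), n_blobs = 120, seed = 1)
pair  <- dual_view_pair(truth, degradation_model(), crossover = 30, seed = 1)

res <- run_fusion_pipeline(pair$view1, pair$view2,
                           run_config(background = 100))
res$plan
#> FusionPlan: z_switch = 31, slope = 3 planes, background = 100 counts
res$report
#>  time channel z_switch slope background     tz    ty     tx      rz       ry    rx
#>     0     ch0       31     3        100 0.0311 0.367 -0.344 0.00618 0.000502 -0.03
```

The pipeline found the switching plane at z = 31, one plane from the
generator's ground-truth crossover (30), and a registration transform
within a fraction of a voxel/degree of the true (zero) misalignment. The
`quality` element holds the two per-plane focus-score profiles behind that
decision, and `res$fused` is the blended stack (same shape as the inputs).

```r
## PSF from a bead field rendered at the instrument's measured resolution
beads <- bead_phantom(seed = 1)      # sigma (0.34, 1.23) um, 0.406 um voxels
measure_psf(beads, threshold = 200)
#> PSFMeasurement: FWHM 0.801 um lateral / 2.896 um axial (29 beads, 0 excluded)

## beam profile -> waist, NA, Rayleigh length (488 nm in water)
xs <- seq(-12, 12, by = 0.2)
characterize_beam(xs, 50 + 800 * exp(-xs^2 / (2 * 1.7215^2)))
#> BeamMeasurement: w0 = 3.443 um, FWHM = 4.054 um, NA_eff = 0.0600, z_r = 101.5 um

## Brownian ensemble: msd3d converges to 6 D t (D = 1 um^2/h)
tracks <- simulate_tracks("brownian", n_tracks = 500, n_steps = 20,
                          dt = 0.1, D = 1, seed = 1)
head(msd3d(tracks), 4)
#>  lag       msd   n
#>  0.0 0.0000000 500
#>  0.1 0.5772575 500
#>  0.2 1.1624430 500
#>  0.3 1.7730404 500
```

The lateral/axial FWHM reproduce the widths the beads were rendered with
(0.80 / 2.90 um), the effective NA of the 3.443-um-waist beam is 0.060, and
the measured MSD tracks the analytic `6 D t` (0.6, 1.2, 1.8 ...) within a
few percent at 500 tracks.

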