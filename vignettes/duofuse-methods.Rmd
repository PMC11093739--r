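---
title: "Dual-view light-sheet fusion and single-cell quantification: methods"
author: "duofuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-view light-sheet fusion and single-cell quantification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duofuse)
```

## The problem

An open-top dual-view light-sheet microscope images a specimen with two
detection objectives facing each other along the optical axis. Each view is
sharp near its own objective and degrades with imaging depth (scattering,
aberration, attenuation), so neither single view resolves single cells
through a thick organoid or gastruloid. The two stacks, however, degrade in
*opposite* directions: combining them plane by plane yields near-uniform
quality through the whole volume. `duofuse` implements that combination and
the quantitative analyses that sit on top of it: optical characterization
of the instrument, and motion and shape statistics of tracked and segmented
cells.

All volumes are indexed `(z, y, x)` with z the detection axis, 0-based plane
indices in every reported quantity, micrometres for space and hours for
time.

## Fusion model

The pipeline runs five stages on a stack pair:

1. **Mirror.** The second camera records mirrored geometry; view 2 is
   flipped along z (configurable to include x) to match view 1's
   handedness.
2. **Rigid registration.** Small mechanical misalignments between the
   objectives are corrected with a 6-degree-of-freedom rigid transform
   `T(p) = R (p - c) + c + t` estimated by maximizing an intensity
   similarity metric. The schedule is deterministic: a centre-of-mass
   translation initialization, then Nelder-Mead refinement on a 2x
   mean-pooled volume followed by full resolution, with trilinear
   interpolation throughout. Normalized cross-correlation is the default
   metric. Mutual information (32-bin joint histogram) is available via
   `register_metric: "mi"`, but in our recovery experiments on seeded
   phantoms the histogram-MI objective is flat enough around pure rotations
   that Nelder-Mead stalls well outside a 0.2 degree error, while NCC
   recovers the same rotations to a few hundredths of a degree; since the
   two views differ only by smooth depth-dependent blur and attenuation
   (approximately a per-plane linear intensity map, which NCC tolerates),
   NCC is the better default for this geometry.
3. **Per-plane quality.** Each plane of both stacks is scored with the
   focus metric below; profiles are smoothed with a centred moving average
   (default window 5 planes, shrink-to-fit at the edges).
4. **Switching plane.** The fused stack should follow whichever view is
   sharper at each depth. `find_switch_plane()` returns the first plane at
   which the opposing view's smoothed score reaches the near view's score.
   If one view dominates everywhere the "fusion" degenerates to that view
   (switch at plane 0 or the last plane); exact ties resolve to the
   smaller index.
5. **Sigmoidal blend.** With weights
   `w2(z) = 1 / (1 + exp(-(z - z_switch) / s))`, `w1 = 1 - w2`, the fused
   stack is `w1 v1 + w2 v2 - b`, clipped at zero. The slope `s` (planes)
   defaults to 3: at typical 1-2 um z-steps this blends over roughly 6 um,
   wide enough to hide the seam and narrow enough not to mix strongly
   degraded planes. The background `b` is a constant camera offset
   (default 0; `background: "auto"` estimates it as the 1st percentile of
   the input stacks). Negative values after subtraction are clipped because
   intensities are photon counts.

The switching plane is computed independently per time point and channel:
as a specimen grows, the optimal crossover moves.

## Focus metric

Image sharpness per plane is the Shannon entropy of the normalized 2D
type-II DCT. The plane mean is subtracted first (so a brighter but equally
blurred plane does not score differently), the orthonormal DCT is taken,
coefficient power is normalized to a probability distribution
`p_k = c_k^2 / sum(c^2)`, and the score is `H = -sum p_k ln p_k`. Defocus
concentrates spectral power at low frequencies and lowers the entropy;
noise and fine structure spread it and raise it. Properties the test suite
asserts: a constant plane scores exactly 0, any plane scores at most
`ln K` with `K` the number of retained coefficients, the score is invariant
to positive rescaling, and growing Gaussian blur never raises it on seeded
noise ensembles. A radial support fraction can restrict the scored
coefficients to the optically meaningful band (default 1.0 = all); an
L2-magnitude normalization variant is available for compatibility with the
autofocus literature (`dcts_norm: "l2"`). Natural logarithms throughout.
Scores are computed on raw planes; the camera offset is removed only at
fusion (mean subtraction makes the score itself offset-free).

## Optical characterization

Line profiles (static beam images, bead profiles) are fitted with
`f(x) = a + b exp(-(x - mu)^2 / (2 sigma^2))` by Levenberg-Marquardt with
moment-based initialization (`a` from the minimum, `b` from the range,
`mu` from the argmax, `sigma` from the second moment of the
offset-subtracted profile). The Jacobian is supplied analytically: with
numeric differentiation, a converged centre within rounding of zero makes
the relative finite-difference step underflow and the solver reports a
spurious singularity on otherwise perfect fits.

Derived quantities use the standard Gaussian-beam relations:

* `FWHM = 2 sigma sqrt(2 ln 2)`. (Note the widely-reprinted variant with
  sigma inside the radical is dimensionally inconsistent - it cannot return
  a length - so the standard form is used.)
* Beam waist `w0 = 2 sigma`: the 1/e^2 intensity radius of a beam whose
  transverse *intensity* profile has standard deviation sigma.
* `NA_eff = n lambda / (pi w0)`; for water (n = 1.33), 488 nm and
  `w0 = 3.443` um this gives 0.060.
* Rayleigh length `z_r = pi w0^2 n / lambda` from the closed form; a
  fit-based route (`fit_beam_widths()`) estimates `w0` and `z_r` from a
  measured width-versus-z caustic instead, and the two agree within 2% on
  simulated beams.

PSF measurement (`measure_psf()`) detects beads as local maxima above a
threshold, drops peak pairs closer than an exclusion radius (default 3
voxels) and beads whose profile window is clipped by the stack border,
fits x- and z-profiles through each remaining bead, converts to FWHM and
averages. On noiseless synthetic bead fields the recovery error is below
2%; under Poisson noise at peak SNR 30 it stays within 5%.

## Track statistics

`msd3d()` implements the ensemble, origin-anchored mean square
displacement `msd(t) = (1/N) sum_i (r_i(t) - r_i(0))^2` - deliberately
*not* the sliding-window time average, which estimates a different
quantity for non-stationary migration. Each track is anchored at its own
first observed frame; tracks contribute only at lags they cover and the
per-lag `N` is reported so the averaging set is transparent. For ballistic
motion the curve is exactly `v^2 t^2`; for 3D Brownian motion it converges
to `6 D t`.

Because it is ambiguous whether a "cell velocity" is a per-step speed or a
track-averaged speed, both are provided: `step_speeds()` (one row per
consecutive observation pair, displacement over elapsed time - frame gaps
divide by the true elapsed time) and `track_speeds()` (per-track mean).
`path_length()` sums consecutive displacements.

## Shape features

2D label masks predicted plane-by-plane are stitched into 3D labels by
intersection-over-union: scanning down the stack, each mask links to the
previous plane's mask of maximal IoU when the IoU reaches the threshold
(default 0.25), one-to-one in descending IoU order; unlinked masks open
new labels. On solid convex phantoms this reproduces the 3D
connected-component count at thresholds up to 0.5, with one caveat worth
knowing: where an object ends in a near-degenerate polar cap (a one-voxel
disk under a much larger one), the cap's IoU with its neighbour falls below
any reasonable threshold and it is split off as its own label - the same
behaviour plane-stitched Cellpose masks show on real data.

Per-region features use the second central moments of the voxel centres
with the physical spacing folded in. Axis lengths are those of the
ellipsoid with the same moments: `2 sqrt(5 lambda)` per eigenvalue
`lambda` (for a solid ellipsoid with semi-axis `a`, the moment along that
axis is `a^2/5`). Each voxel's own second moment (`s^2/12` per axis) is
added so single-voxel-thick regions keep a positive minor axis; this is
also what makes the discrete cube's moments match the continuous cube's
exactly. False-segmentation filtering (`filter_regions()`) applies closed
bounds on volume and both axis lengths; the bounds ship unset because any
cut-off is an experiment-specific choice that should be stated, not
defaulted.

## Synthetic data

The generators produce every input the pipeline consumes, with known
ground truth and bit-reproducible seeding:

* `blob_phantom()`: random bright Gaussian blobs - structure at every
  depth for the focus and registration metrics.
* `dual_view_pair()`: blur growing linearly with distance from each view's
  near surface (`sigma(z) = sigma0 + k z` voxels; linear because it is the
  simplest monotone profile that produces a unique quality crossover),
  exponential attenuation per micrometre of depth, optional Poisson noise
  applied after blur and attenuation (the camera-physics order), then the
  per-view constant background. The two blur rates are solved so the
  widths are equal exactly at the requested crossover plane, which is
  returned as ground truth. View 2 is displaced by the requested
  misalignment and recorded mirrored along z.
* `bead_phantom()`: beads at uniform sub-voxel positions (margin 5 sigma
  from every border, minimum pairwise separation with bounded retries)
  rendered as anisotropic Gaussians.
* `simulate_tracks()`: ballistic (`r(t) = r0 + v t u`, random unit
  directions) or Brownian (Gaussian increments of variance `2 D dt` per
  axis).
* `ellipsoid_labels()`: voxelized non-overlapping ellipsoids by the
  implicit-equation test at voxel centres.

Default study conditions used by the test suite and the acceptance script:
50-plane fusion phantoms (64 x 64 laterally, keeping each pipeline run in
the low seconds), near-surface blur 0.5 voxels growing at 0.1 voxels per
plane, attenuation 0.01 per um, camera offset 100 counts; bead fields with
PSF sigma (0.34, 1.23) um at isotropic 0.406 um spacing, matching the
instrument's measured 0.8 um lateral / 2.9 um axial FWHM; Brownian
ensembles of 500 tracks at `D = 1` um^2/h, `dt = 0.1` h; ballistic checks
at `v = 2` um/h.

What the generators deliberately do not model: striping and shadowing
(handled optically by dual illumination), scattering kernels beyond
Gaussian blur, depth-dependent PSF anisotropy changes, sample motion, and
segmentation errors. Passing tests therefore demonstrate correctness of
the algorithms under their stated assumptions, not performance on real
tissue.

## Numerical choices and degenerate inputs

* The DCT is computed by exact orthonormal matrix multiplication (cached
  per plane size); an all-zero plane after mean subtraction scores 0 by
  definition rather than erroring.
* Registration is fully deterministic (no stochastic sampling); identical
  inputs give bit-identical transforms. Constant images are rejected with
  a "no structure to align" error; a sub-10% overlap at initialization is
  reported as a convergence failure with the metric value.
* Resampling is trilinear with a configurable out-of-bounds fill (the
  config background). Interpolation slightly smooths the moving view; with
  live registration the fused-vs-worse-view quality margin can dip by
  ~0.03 entropy units near the switching plane, which is why quality
  invariants are validated on aligned pairs.
* Sub-voxel switch planes are not interpolated: z_switch is an integer
  plane index, ties toward the smaller index.
* TIFF storage is 16-bit unsigned counts in [0, 65535]; round trips are
  exact at that precision. Out-of-range or non-finite intensities are
  rejected before writing.
* Gaussian fits report `|sigma|`; degenerate (constant) profiles error
  rather than returning a zero width.

## Limitations

* Fusion switches between views rather than deconvolving them; there is no
  multiview deconvolution, affine or deformable registration.
* The registration basin of attraction is a few voxels / a few degrees -
  adequate for mechanical misalignment between rigidly mounted objectives,
  not for gross initial misalignment.
* Filtering thresholds, chamber geometry corrections and any real-data
  intensity calibration are out of scope; the package consumes label
  images and track tables produced by external tools (e.g. Cellpose,
  Mastodon exports).
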