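#' Fusion plan: everything needed to blend two registered views
#'
#' @param z_switch 0-based plane index where the blend is centered.
#' @param slope sigmoid steepness in planes (> 0).
#' @param background constant camera offset subtracted after blending
#'   (counts, >= 0).
#' @param transform the [rigid_transform()] applied to view 2.
#' @param flip_axes axes view 2 was mirrored along.
#' @param n_planes plane count, used to validate `z_switch`.
#' @return An object of class `FusionPlan`.
#' @export
fusion_plan <- function(z_switch, slope = 3, background = 0,
                        transform = rigid_transform(), flip_axes = "z",
                        n_planes = NULL) {
  check_positive(slope, "slope")
  if (background < 0) stopf("background must be >= 0")
  if (z_switch < 0) stopf("z_switch must be >= 0")
  if (!is.null(n_planes) && z_switch >= n_planes)
    stopf("z_switch (%s) must be < plane count (%d)", z_switch, n_planes)
  structure(list(z_switch = z_switch, slope = slope, background = background,
                 transform = transform, flip_axes = flip_axes),
            class = "FusionPlan")
}

#' @export
print.FusionPlan <- function(x, ...) {
  cat(sprintf("FusionPlan: z_switch = %s, slope = %g planes, background = %g counts\n",
              format(x$z_switch), x$slope, x$background))
  invisible(x)
}

#' Depth at which to switch detection views
#'
#' Scans the difference of the two per-plane quality profiles and returns
#' the smallest 0-based plane index at which the sign flips away from the
#' dominant near-side (low-z) sign, i.e. the first depth where the opposing
#' view scores at least as well. Without a crossover the blend degenerates
#' to the better single view: the last plane index when view 1 dominates
#' everywhere, 0 when view 2 does. Exact ties resolve toward the smaller
#' index (two identical profiles give 0).
#'
#' @param p1,p2 [quality_profile()] objects (or plain score vectors) of
#'   equal length >= 2 for view 1 and view 2.
#' @return A single 0-based plane index.
#' @examples
#' find_switch_plane(c(3, 2, 1, 0), c(0, 1, 2, 3))  # 2
#' @export
find_switch_plane <- function(p1, p2) {
  s1 <- if (inherits(p1, "QualityProfile")) p1$scores else as.numeric(p1)
  s2 <- if (inherits(p2, "QualityProfile")) p2$scores else as.numeric(p2)
  if (length(s1) != length(s2))
    stopf("quality profiles differ in length (%d vs %d)",
          length(s1), length(s2))
  n <- length(s1)
  if (n < 2L) stopf("need at least 2 planes to place a switching plane")
  d <- s1 - s2
  nz <- which(d != 0)
  if (!length(nz)) return(0L)           # identical profiles: tie -> 0
  s <- sign(d[nz[1]])
  for (i in (nz[1] + 1L):n) {
    if (i > n) break
    if (s * d[i] <= 0) return(i - 1L)   # first opposing (or tied) plane
  }
  if (s > 0) n - 1L else 0L
}

#' Sigmoidal blending weights across depth
#'
#' `w2(z) = 1 / (1 + exp(-(z - z_switch) / slope))`, `w1 = 1 - w2`: view 1
#' dominates below the switching plane, view 2 above, with a blend zone of
#' a few planes' width hiding the seam.
#'
#' @param n_planes number of z planes.
#' @param z_switch switching plane (0-based; may be fractional).
#' @param slope steepness in planes (> 0); small values approach a hard
#'   step at `z_switch`.
#' @return A list with numeric vectors `w1` and `w2` of length `n_planes`;
#'   `w1 + w2 == 1` at every plane.
#' @export
sigmoid_weights <- function(n_planes, z_switch, slope = 3) {
  check_positive(slope, "slope")
  z <- seq_len(n_planes) - 1
  w2 <- 1 / (1 + exp(-(z - z_switch) / slope))
  list(w1 = 1 - w2, w2 = w2)
}

#' Fuse two registered views into one stack
#'
#' `fused(z) = w1(z) view1(z) + w2(z) view2(z) - background`, clipped at 0.
#' View 2 must already be flipped and resampled into view 1's frame.
#'
#' @param view1,view2 [volume_stack()] objects of identical shape.
#' @param plan a [fusion_plan()].
#' @return The fused `VolumeStack` (`view_id = "fused"`).
#' @export
fuse_stacks <- function(view1, view2, plan) {
  view1 <- as_volume(view1, "view1"); view2 <- as_volume(view2, "view2")
  if (!inherits(plan, "FusionPlan")) stopf("'plan' must be a FusionPlan")
  if (!identical(dim(view1$data), dim(view2$data)))
    stopf("view shapes differ: %s vs %s",
          paste(dim(view1$data), collapse = "x"),
          paste(dim(view2$data), collapse = "x"))
  nz <- dim(view1$data)[1]
  if (plan$z_switch >= nz) stopf("z_switch (%s) outside stack (%d planes)",
                                 format(plan$z_switch), nz)
  w <- sigmoid_weights(nz, plan$z_switch, plan$slope)
  out <- view1$data * w$w1 + view2$data * w$w2  # weights recycle along z
  out <- pmax(out - plan$background, 0)
  dim(out) <- dim(view1$data)
  fused <- view1
  fused$data <- out
  fused$view_id <- "fused"
  fused
}

#' Run the full dual-view fusion pipeline on one stack pair
#'
#' Stages, in order: mirror view 2 ([flip_opposing_view()]), rigid
#' registration onto view 1 ([register_rigid()]), resampling
#' ([resample()]), per-plane quality scoring of both views
#' ([quality_profile()]), switching-plane selection
#' ([find_switch_plane()]) and sigmoidal fusion with constant background
#' subtraction ([fuse_stacks()]). Deterministic given fixed inputs and
#' config.
#'
#' @param view1,view2 `VolumeStack` objects or TIFF paths (read with the
#'   config's spacing).
#' @param config a [run_config()].
#' @return A list with `fused` (VolumeStack), `plan` (FusionPlan),
#'   `quality` (data.frame `z`, `score_view1`, `score_view2`) and `report`
#'   (one row per (time, channel): z_switch, slope, background, transform
#'   parameters).
#' @export
run_fusion_pipeline <- function(view1, view2, config = run_config()) {
  config <- validate_config(config)
  sp <- config_spacing(config)
  if (is.character(view1)) view1 <- read_volume(view1, sp, "view1")
  if (is.character(view2)) view2 <- read_volume(view2, sp, "view2")
  view1 <- as_volume(view1, "view1"); view2 <- as_volume(view2, "view2")

  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s': %s", name, conditionMessage(e)))

  v2 <- stage("flip", flip_opposing_view(view2, config$flip_axes))
  if (!identical(dim(view1$data), dim(v2$data)))
    stopf("view shapes differ after flip: %s vs %s",
          paste(dim(view1$data), collapse = "x"),
          paste(dim(v2$data), collapse = "x"))

  background <- config$background
  if (identical(background, "auto"))
    background <- as.numeric(quantile(c(view1$data, v2$data), 0.01))

  if (config$register == "off") {
    tr <- rigid_transform()
  } else {
    tr <- stage("register",
                register_rigid(v2, view1, metric = config$register_metric,
                               nbins = config$register_bins,
                               maxit = config$register_maxit))
    v2 <- stage("resample", resample(v2, tr, background = background))
  }

  q1 <- stage("quality", quality_profile(view1, config$dct_support_fraction,
                                         config$smoothing_window,
                                         norm = config$dcts_norm))
  q2 <- stage("quality", quality_profile(v2, config$dct_support_fraction,
                                         config$smoothing_window,
                                         norm = config$dcts_norm))
  zs <- stage("switch", find_switch_plane(q1, q2))
  plan <- fusion_plan(zs, config$sigmoid_slope, background, tr,
                      config$flip_axes, n_planes = dim(view1$data)[1])
  fused <- stage("fuse", fuse_stacks(view1, v2, plan))

  report <- data.frame(
    time = view1$time_index %||% 0L,
    channel = view1$channel %||% "ch0",
    z_switch = zs, slope = plan$slope, background = background,
    tz = tr$translation[1], ty = tr$translation[2], tx = tr$translation[3],
    rz = tr$rotation[1], ry = tr$rotation[2], rx = tr$rotation[3],
    row.names = NULL)
  list(fused = fused, plan = plan,
       quality = data.frame(z = seq_along(q1$scores) - 1L,
                            score_view1 = q1$scores,
                            score_view2 = q2$scores),
       report = report)
}
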