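metric_code <- function(metric) match(metric, c("ncc", "mi")) - 1L

## Similarity of fixed vs moving sampled through `par` (rz, ry, rx in
## degrees, tz, ty, tx in um) on given arrays. Higher is better.
eval_metric <- function(par, fixed, moving, spacing, center, metric, nbins,
                        franges, mranges, stride = 1L) {
  tr <- rigid_transform(par[1:3], par[4:6], center)
  M <- voxel_matrix(tr, spacing)
  cpp_affine_metric(fixed, moving, dim(fixed), M, metric_code(metric),
                    as.integer(nbins), franges[1], franges[2], mranges[1],
                    mranges[2], as.integer(stride))
}

#' Rigid registration of two volumes
#'
#' Estimates the 6-degree-of-freedom rigid transform that, applied through
#' [resample()], brings `moving` into the frame of `fixed`. The optimizer
#' maximizes an intensity similarity metric (normalized cross-correlation
#' by default, mutual information available) with a deterministic schedule:
#' a centre-of-mass translation initialization, then Nelder-Mead refinement
#' on a 2x mean-pooled level followed by the full-resolution level. There is
#' no stochastic sampling, so results are reproducible bit-for-bit.
#'
#' @param moving,fixed [volume_stack()] objects with identical voxel spacing
#'   and overlapping content. Designed for the small mechanical
#'   misalignments between two opposing detection objectives (a few voxels,
#'   a degree or two).
#' @param metric `"mi"` or `"ncc"`.
#' @param nbins joint-histogram bins for mutual information.
#' @param maxit Nelder-Mead iteration cap per pyramid level.
#' @param pyramid integer pooling factors, coarse to fine.
#' @return A [rigid_transform()] whose rotation center is the volume's
#'   physical center; attribute `metric_value` holds the final similarity.
#' @export
register_rigid <- function(moving, fixed, metric = c("ncc", "mi"),
                           nbins = 32L, maxit = 400L, pyramid = c(2L, 1L)) {
  moving <- as_volume(moving, "moving"); fixed <- as_volume(fixed, "fixed")
  metric <- match.arg(metric)
  if (!isTRUE(all.equal(moving$spacing, fixed$spacing)))
    stopf("moving and fixed must have the same voxel spacing")
  if (!identical(dim(moving$data), dim(fixed$data)))
    stopf("moving and fixed must have the same shape")
  if (sd(fixed$data) == 0 || sd(moving$data) == 0)
    stopf("registration failure: constant image (no structure to align)")
  spacing <- fixed$spacing
  d <- dim(fixed$data)
  center <- (d - 1) / 2 * spacing

  ## centre-of-mass translation init, on background-suppressed intensities
  com <- function(a) {
    w <- pmax(a - median(a), 0)
    s <- sum(w)
    if (s == 0) return((d - 1) / 2)
    c(sum(w * (slice.index(a, 1) - 1)), sum(w * (slice.index(a, 2) - 1)),
      sum(w * (slice.index(a, 3) - 1))) / s
  }
  t0 <- (com(moving$data) - com(fixed$data)) * spacing
  par <- c(0, 0, 0, t0)

  for (f in pyramid) {
    fx <- pool3(fixed$data, f)
    mv <- pool3(moving$data, f)
    sp <- spacing * f
    franges <- range(fx); mranges <- range(mv)
    obj <- function(p)
      -eval_metric(p, fx, mv, sp, center, metric, nbins, franges, mranges)
    v0 <- obj(par)
    if (!is.finite(v0))
      stopf("registration failure: volumes do not overlap at initialization (metric %g)", -v0)
    ## restart once at the finest level: a fresh simplex around the first
    ## optimum polishes the collapse-prone Nelder-Mead solution
    n_runs <- if (f == min(pyramid)) 2L else 1L
    for (run in seq_len(n_runs)) {
      fit <- optim(par, obj, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = 1e-10,
                                  parscale = c(rep(0.5, 3),
                                               rep(mean(sp) / 2, 3))))
      if (is.finite(fit$value) && fit$value <= v0) {
        par <- fit$par
        v0 <- fit$value
      }
    }
  }
  final <- -obj(par)
  if (!is.finite(final))
    stopf("registration failure: no overlapping content (final metric %g)",
          final)
  out <- rigid_transform(par[1:3], par[4:6], center)
  attr(out, "metric_value") <- final
  attr(out, "metric") <- metric
  out
}
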