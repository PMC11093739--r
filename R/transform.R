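#' Rigid-body transform in physical (micrometre) coordinates
#'
#' Maps a point `p` (ordered `(z, y, x)`, micrometres) of the fixed frame to
#' the location sampled in the moving volume:
#' `T(p) = R (p - center) + center + translation`, with `R` the rotation by
#' the given angles applied in z-y-x order about the physical axes.
#'
#' @param rotation angles in degrees about the `(z, y, x)` axes.
#' @param translation micrometre shifts along `(z, y, x)`.
#' @param center rotation center in micrometres, `(z, y, x)`.
#' @return An object of class `RigidTransform`.
#' @examples
#' t <- rigid_transform(translation = c(1, 0, 0))
#' compose_transforms(t, invert_transform(t))  # identity
#' @export
rigid_transform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  rotation <- as.numeric(rotation); translation <- as.numeric(translation)
  center <- as.numeric(center)
  if (length(rotation) != 3L || length(translation) != 3L ||
      length(center) != 3L)
    stopf("rotation, translation and center must each have 3 components")
  if (!all(is.finite(c(rotation, translation, center))))
    stopf("transform parameters must be finite")
  structure(list(rotation = setNames(rotation, c("z", "y", "x")),
                 translation = setNames(translation, c("z", "y", "x")),
                 center = setNames(center, c("z", "y", "x"))),
            class = "RigidTransform")
}

#' @export
print.RigidTransform <- function(x, ...) {
  cat(sprintf("RigidTransform: rot (deg) z=%.4g y=%.4g x=%.4g | shift (um) z=%.4g y=%.4g x=%.4g\n",
              x$rotation[1], x$rotation[2], x$rotation[3],
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

## Rotation matrix acting on (z, y, x)-ordered physical vectors.
## Built as Rz(az) Ry(ay) Rx(ax) in conventional (x, y, z) space and
## conjugated with the axis-reversal permutation.
rotation_matrix_zyx <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cz <- cos(a[1]); sz <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cx <- cos(a[3]); sx <- sin(a[3])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  R_xyz <- Rz %*% Ry %*% Rx
  P <- matrix(c(0, 0, 1, 0, 1, 0, 1, 0, 0), 3, 3)  # (z,y,x) <-> (x,y,z)
  P %*% R_xyz %*% P
}

## Euler angles (deg, z-y-x order) from a rotation matrix in (z,y,x) space.
angles_from_matrix <- function(Rzyx) {
  P <- matrix(c(0, 0, 1, 0, 1, 0, 1, 0, 0), 3, 3)
  R <- P %*% Rzyx %*% P  # back to (x, y, z) space
  ry <- asin(max(-1, min(1, -R[3, 1])))
  rx <- atan2(R[3, 2], R[3, 3])
  rz <- atan2(R[2, 1], R[1, 1])
  c(rz, ry, rx) * 180 / pi
}

#' Homogeneous 4x4 matrix of a rigid transform
#'
#' Acts on physical column vectors `(z, y, x, 1)` in micrometres.
#'
#' @param transform a [rigid_transform()].
#' @export
transform_matrix <- function(transform) {
  R <- rotation_matrix_zyx(transform$rotation)
  d <- as.numeric(-R %*% transform$center + transform$center +
                    transform$translation)
  M <- rbind(cbind(R, d), c(0, 0, 0, 1))
  dimnames(M) <- NULL
  M
}

matrix_to_transform <- function(M, center = c(0, 0, 0)) {
  R <- M[1:3, 1:3]
  t <- M[1:3, 4] + as.numeric(R %*% center) - center
  rigid_transform(angles_from_matrix(R), t, center)
}

#' Compose and invert rigid transforms
#'
#' `compose_transforms(t2, t1)` returns the transform equivalent to applying
#' `t1` first, then `t2`. Composition with the inverse returns the identity
#' to floating-point precision.
#'
#' @param t1,t2,transform [rigid_transform()] objects.
#' @return A `RigidTransform` (reported about `t1`'s / the input's center).
#' @export
compose_transforms <- function(t2, t1) {
  matrix_to_transform(transform_matrix(t2) %*% transform_matrix(t1),
                      t1$center)
}

#' @rdname compose_transforms
#' @export
invert_transform <- function(transform) {
  matrix_to_transform(solve(transform_matrix(transform)), transform$center)
}

## 3x4 voxel-space affine (0-based voxel indices, (z,y,x) order) for use by
## the compiled resampler: src_voxel = S^-1 (R (S v) + d).
voxel_matrix <- function(transform, spacing) {
  M <- transform_matrix(transform)
  S <- diag(spacing)
  A <- solve(S) %*% M[1:3, 1:3] %*% S
  b <- solve(S) %*% M[1:3, 4]
  cbind(A, b)
}

#' Resample a stack through a rigid transform
#'
#' Trilinear interpolation of the moving stack onto its own grid after
#' applying the transform; voxels that map outside the volume are set to
#' `background`.
#'
#' @param stack a [volume_stack()] to resample.
#' @param transform a [rigid_transform()] (fixed frame -> sampled location).
#' @param background fill value for out-of-bounds voxels (counts).
#' @return The resampled `VolumeStack`.
#' @export
resample <- function(stack, transform, background = 0) {
  stack <- as_volume(stack)
  if (!inherits(transform, "RigidTransform"))
    stopf("'transform' must be a RigidTransform")
  M <- voxel_matrix(transform, stack$spacing)
  out <- stack
  res <- cpp_affine_resample(as.vector(stack$data), dim(stack$data), M,
                             background)
  out$data <- array(res, dim(stack$data))
  out
}
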