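#' Construct a 3D intensity volume
#'
#' The package-wide container for one image stack from one detection view.
#' Data are indexed `(z, y, x)` with z the detection axis and 0-based plane
#' arithmetic in all plane indices reported by the fusion code; spacing is
#' the physical voxel size in micrometres per axis, in the same `(z, y, x)`
#' order.
#'
#' @param data 3D numeric array indexed `(z, y, x)`; all values finite.
#' @param spacing numeric length-3, micrometres per voxel along `(z, y, x)`.
#' @param view_id one of `"view1"`, `"view2"`, `"fused"`.
#' @param time_index optional non-negative integer time point.
#' @param channel optional channel label.
#' @return An object of class `VolumeStack`.
#' @examples
#' v <- volume_stack(array(0, c(5, 8, 8)), spacing = c(2, 0.406, 0.406))
#' dim(v$data)
#' @export
volume_stack <- function(data, spacing = c(1, 1, 1), view_id = "view1",
                         time_index = NULL, channel = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("'data' must be a 3D array indexed (z, y, x)")
  if (any(dim(data) < 1L)) stopf("all dimensions must be >= 1")
  if (!all(is.finite(data))) stopf("intensities must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L) stopf("'spacing' must have 3 components (z, y, x)")
  check_positive(spacing, "spacing")
  view_id <- match.arg(view_id, c("view1", "view2", "fused"))
  if (!is.null(time_index)) {
    time_index <- as.integer(time_index)
    if (is.na(time_index) || time_index < 0L)
      stopf("'time_index' must be a non-negative integer")
  }
  structure(list(data = data, spacing = setNames(spacing, c("z", "y", "x")),
                 view_id = view_id, time_index = time_index,
                 channel = channel),
            class = "VolumeStack")
}

#' @export
print.VolumeStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("VolumeStack [%s]: %d x %d x %d (z, y, x), spacing %.4g x %.4g x %.4g um\n",
              x$view_id, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.VolumeStack <- function(x) dim(x$data)

as_volume <- function(x, what = "stack") {
  if (inherits(x, "VolumeStack")) return(x)
  stopf("'%s' must be a VolumeStack", what)
}

#' Construct a 3D label volume
#'
#' Integer-valued segmentation volume; 0 is background and is never counted
#' as a region.
#'
#' @param labels 3D array of non-negative integers indexed `(z, y, x)`.
#' @param spacing micrometres per voxel along `(z, y, x)`.
#' @return An object of class `LabelVolume`.
#' @export
label_volume <- function(labels, spacing = c(1, 1, 1)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stopf("'labels' must be a 3D array indexed (z, y, x)")
  if (!all(is.finite(labels)) || any(labels < 0) ||
      any(labels != round(labels)))
    stopf("labels must be non-negative integers")
  spacing <- as.numeric(spacing)
  check_positive(spacing, "spacing")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels,
                 spacing = setNames(spacing, c("z", "y", "x"))),
            class = "LabelVolume")
}

#' @export
print.LabelVolume <- function(x, ...) {
  d <- dim(x$labels)
  ids <- setdiff(unique(as.vector(x$labels)), 0L)
  cat(sprintf("LabelVolume: %d x %d x %d (z, y, x), %d labels\n",
              d[1], d[2], d[3], length(ids)))
  invisible(x)
}

#' Mirror a stack recorded by the opposing detection objective
#'
#' The two detection objectives face each other along the optical (z) axis,
#' so the second view records a mirrored geometry. Flipping the listed axes
#' brings it into the first view's handedness before rigid registration.
#'
#' @param stack a [volume_stack()].
#' @param flip_axes character subset of `c("z", "x")`; may be empty.
#' @return The flipped `VolumeStack` (spacing unchanged).
#' @examples
#' v <- volume_stack(array(seq_len(3 * 2 * 2), c(3, 2, 2)))
#' f <- flip_opposing_view(v, "z")
#' all(f$data[1, , ] == v$data[3, , ])
#' @export
flip_opposing_view <- function(stack, flip_axes = "z") {
  stack <- as_volume(stack)
  flip_axes <- as.character(flip_axes)
  if (!all(flip_axes %in% c("z", "x")))
    stopf("flip_axes must be a subset of {z, x}, got: %s",
          paste(flip_axes, collapse = ", "))
  d <- dim(stack$data)
  iz <- if ("z" %in% flip_axes) rev(seq_len(d[1])) else seq_len(d[1])
  ix <- if ("x" %in% flip_axes) rev(seq_len(d[3])) else seq_len(d[3])
  out <- stack
  out$data <- stack$data[iz, , ix, drop = FALSE]
  out
}
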