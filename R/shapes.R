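#' Stitch per-plane 2D label masks into a 3D label volume
#'
#' Cell segmentation networks often predict 2D masks plane by plane; this
#' links masks across adjacent planes by mask overlap. Scanning top-down in
#' z, each mask in plane z+1 is linked to the plane-z mask of maximal
#' intersection-over-union, provided the IoU reaches `overlap_threshold`
#' and neither mask is already linked (one-to-one, highest IoU first).
#' Unlinked masks start new 3D labels. Output ids are consecutive from 1.
#'
#' @param plane_labels list of 2D integer label matrices (0 = background),
#'   all of the same shape, ordered by z; or a 3D array indexed (z, y, x).
#' @param overlap_threshold minimum IoU in `[0, 1]` to link two masks.
#' @param spacing micrometres per voxel along `(z, y, x)`.
#' @return A [label_volume()].
#' @export
stitch_planes <- function(plane_labels, overlap_threshold = 0.25,
                          spacing = c(1, 1, 1)) {
  if (is.array(plane_labels) && length(dim(plane_labels)) == 3L)
    plane_labels <- lapply(seq_len(dim(plane_labels)[1]),
                           function(z) plane_labels[z, , ])
  if (!length(plane_labels)) stopf("no planes given")
  d <- dim(plane_labels[[1]])
  if (any(!vapply(plane_labels, function(p)
    is.matrix(p) && identical(dim(p), d), logical(1))))
    stopf("all planes must be matrices of the same shape")
  if (overlap_threshold < 0 || overlap_threshold > 1)
    stopf("overlap_threshold must be in [0, 1]")

  nz <- length(plane_labels)
  out <- array(0L, c(nz, d[1], d[2]))
  next_id <- 1L

  assign_plane <- function(cur, prev_global) {
    ids <- setdiff(unique(as.vector(cur)), 0)
    gl <- matrix(0L, d[1], d[2])
    if (!length(ids)) return(list(plane = gl, next_id = next_id))
    mapped <- setNames(rep(NA_integer_, length(ids)), ids)
    if (!is.null(prev_global)) {
      both <- cur > 0 & prev_global > 0
      if (any(both)) {
        inter <- table(prev = prev_global[both], cur = cur[both])
        a_prev <- table(prev_global[prev_global > 0])
        a_cur <- table(cur[cur > 0])
        cand <- as.data.frame(inter, stringsAsFactors = FALSE)
        cand <- cand[cand$Freq > 0, , drop = FALSE]
        cand$iou <- cand$Freq /
          (as.numeric(a_prev[cand$prev]) + as.numeric(a_cur[cand$cur]) -
             cand$Freq)
        cand <- cand[cand$iou >= overlap_threshold, , drop = FALSE]
        cand <- cand[order(-cand$iou), , drop = FALSE]
        used_prev <- character(0)
        for (k in seq_len(nrow(cand))) {
          cu <- cand$cur[k]; pr <- cand$prev[k]
          if (!is.na(mapped[cu]) || pr %in% used_prev) next
          mapped[cu] <- as.integer(pr)
          used_prev <- c(used_prev, pr)
        }
      }
    }
    for (id in names(mapped)) {
      if (is.na(mapped[id])) {
        mapped[id] <- next_id
        next_id <<- next_id + 1L
      }
      gl[cur == as.numeric(id)] <- mapped[id]
    }
    list(plane = gl)
  }

  prev <- NULL
  for (z in seq_len(nz)) {
    res <- assign_plane(plane_labels[[z]], prev)
    out[z, , ] <- res$plane
    prev <- res$plane
  }
  ## relabel to consecutive ids
  ids <- sort(setdiff(unique(as.vector(out)), 0L))
  lut <- integer(max(c(ids, 0L)) + 1L)
  lut[ids + 1L] <- seq_along(ids)
  out[] <- ifelse(out == 0L, 0L, lut[out + 1L])
  label_volume(out, spacing)
}

#' 3D shape features per labelled region
#'
#' Per label: physical volume, centroid, and major/minor axis lengths of
#' the ellipsoid with the same second central moments as the region
#' (axis length `2 sqrt(5 lambda)` for moment eigenvalue `lambda`, the
#' 3D ellipsoid-equivalent scaling). Anisotropic voxel spacing is folded
#' into the moments, and each voxel's own extent (`s^2 / 12` per axis)
#' is included so thin regions keep positive widths.
#'
#' @param labels a [label_volume()].
#' @return A `RegionFeatures` data.frame: `label`, `volume` (um^3),
#'   `major_axis`, `minor_axis` (um), `axis_ratio` (major/minor), and the
#'   centroid `centroid_z/y/x` (um). Empty label volume gives zero rows.
#' @export
region_features <- function(labels) {
  if (!inherits(labels, "LabelVolume")) stopf("'labels' must be a LabelVolume")
  a <- labels$labels
  sp <- labels$spacing
  vox <- prod(sp)
  ids <- sort(setdiff(unique(as.vector(a)), 0L))
  rows <- lapply(ids, function(id) {
    idx <- which(a == id, arr.ind = TRUE)  # columns (z, y, x), 1-based
    phys <- sweep(idx - 1, 2, sp, `*`)
    n <- nrow(phys)
    ctr <- colMeans(phys)
    cc <- sweep(phys, 2, ctr)
    cov <- crossprod(cc) / n + diag(sp^2 / 12)
    ev <- sort(eigen(cov, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev <- pmax(ev, 0)
    data.frame(label = id, volume = n * vox,
               major_axis = 2 * sqrt(5 * ev[1]),
               minor_axis = 2 * sqrt(5 * ev[3]),
               axis_ratio = sqrt(ev[1] / ev[3]),
               centroid_z = ctr[1], centroid_y = ctr[2], centroid_x = ctr[3])
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(), volume = numeric(), major_axis = numeric(),
               minor_axis = numeric(), axis_ratio = numeric(),
               centroid_z = numeric(), centroid_y = numeric(),
               centroid_x = numeric())
  rownames(out) <- NULL
  class(out) <- c("RegionFeatures", "data.frame")
  out
}

#' Exclude false segmentations by volume and axis-length bounds
#'
#' Keeps regions whose volume and both axis lengths lie inside the closed
#' bounds. No defaults are imposed beyond keep-everything; cut-offs are a
#' per-experiment choice.
#'
#' @param features a [region_features()] table.
#' @param volume length-2 closed bounds on volume (um^3).
#' @param axis length-2 closed bounds applying to both major and minor axis
#'   lengths (um).
#' @return The surviving rows, with attributes `n_kept` and `n_dropped`.
#' @export
filter_regions <- function(features, volume = c(0, Inf), axis = c(0, Inf)) {
  if (!is.data.frame(features)) stopf("'features' must be a RegionFeatures table")
  if (length(volume) != 2L || length(axis) != 2L)
    stopf("bounds must be length-2 (min, max)")
  if (volume[1] > volume[2] || axis[1] > axis[2])
    stopf("bounds are inverted (min > max)")
  keep <- features$volume >= volume[1] & features$volume <= volume[2] &
    features$major_axis >= axis[1] & features$major_axis <= axis[2] &
    features$minor_axis >= axis[1] & features$minor_axis <= axis[2]
  out <- features[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}
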