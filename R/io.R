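MAX_COUNTS <- 65535

#' Read a multi-page TIFF into a VolumeStack
#'
#' One TIFF page per z-plane. Pixel values are returned as floating-point
#' camera counts in `[0, 65535]` (the package stores volumes as 16-bit
#' unsigned TIFF).
#'
#' @param path path to a multi-page TIFF file.
#' @param spacing micrometres per voxel along `(z, y, x)`.
#' @param view_id,time_index,channel passed to [volume_stack()].
#' @return A `VolumeStack` with one plane per TIFF page.
#' @seealso [write_volume()]
#' @export
read_volume <- function(path, spacing = c(1, 1, 1), view_id = "view1",
                        time_index = NULL, channel = NULL) {
  check_positive(spacing, "spacing")
  if (!file.exists(path)) stopf("cannot read TIFF: no such file '%s'", path)
  pages <- tryCatch(readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      stopf("cannot read TIFF '%s': %s", path,
                            conditionMessage(e)))
  if (is.matrix(pages) || is.array(pages)) pages <- list(pages)
  if (length(pages) == 0L) stopf("TIFF '%s' contains zero pages", path)
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
    stopf("TIFF '%s' has non-greyscale pages; expected one 2D page per plane",
          path)
  d <- dim(pages[[1]])
  arr <- array(0, c(length(pages), d[1], d[2]))
  for (z in seq_along(pages)) {
    p <- pages[[z]]
    if (!identical(dim(p), d)) stopf("TIFF '%s': page sizes differ", path)
    ## readTIFF(as.is = FALSE) would rescale; as.is = TRUE keeps raw counts,
    ## but falls back to [0,1] doubles for float TIFFs - rescale those too.
    if (is.double(p) && max(p) <= 1) p <- p * MAX_COUNTS
    arr[z, , ] <- p
  }
  volume_stack(arr, spacing, view_id = view_id, time_index = time_index,
               channel = channel)
}

#' Write a VolumeStack as a multi-page 16-bit TIFF
#'
#' Intensities must be finite and inside `[0, 65535]`; they are rounded to
#' integer counts, so [read_volume()] inverts this exactly for integer data.
#'
#' @param stack a [volume_stack()].
#' @param path output file path; the parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(stack, path) {
  stack <- as_volume(stack)
  if (!dir.exists(dirname(path)))
    stopf("cannot write '%s': directory does not exist", path)
  a <- stack$data
  if (!all(is.finite(a))) stopf("stack contains non-finite values")
  if (min(a) < 0 || max(a) > MAX_COUNTS)
    stopf("intensities outside [0, %d] cannot be stored as 16-bit counts",
          MAX_COUNTS)
  planes <- lapply(seq_len(dim(a)[1]),
                   function(z) round(a[z, , ]) / MAX_COUNTS)
  ok <- tryCatch(writeTIFF(planes, path, bits.per.sample = 16L),
                 error = function(e)
                   stopf("cannot write TIFF '%s': %s", path,
                         conditionMessage(e)))
  invisible(path)
}

#' Read / write a 3D label volume as multi-page TIFF
#'
#' Labels are stored as 16-bit integers (ids up to 65535).
#'
#' @param path TIFF file path.
#' @param spacing micrometres per voxel along `(z, y, x)`.
#' @return A `LabelVolume`.
#' @export
read_label_volume <- function(path, spacing = c(1, 1, 1)) {
  v <- read_volume(path, spacing)
  label_volume(array(as.integer(round(v$data)), dim(v$data)), spacing)
}

#' @rdname read_label_volume
#' @param labels a [label_volume()].
#' @export
write_label_volume <- function(labels, path) {
  if (!inherits(labels, "LabelVolume")) stopf("'labels' must be a LabelVolume")
  write_volume(volume_stack(labels$labels + 0, labels$spacing), path)
}

## Column sniffing for track tables: the Mastodon CSV export names columns
## like "Spot track ID", "Spot frame", "Spot position X"; plain exports use
## track_id/frame/x/y/z. Matching is case-insensitive on cleaned names.
find_column <- function(nms, patterns, what) {
  low <- tolower(gsub("[^a-z0-9]+", ".", tolower(nms)))
  for (p in patterns) {
    hit <- grep(p, low)
    if (length(hit)) return(hit[1])
  }
  stopf("track table is missing a column for %s (looked for %s)",
        what, paste(patterns, collapse = ", "))
}

#' Read a cell-track table exported as CSV
#'
#' Expects one row per spot with columns for track id, frame and the 3D
#' position in micrometres; the column sniffing accepts both plain
#' `track_id, frame, x, y, z` headers and the Mastodon spot-export naming.
#' Any columns whose name contains "intensity" or "mean" are attached as
#' per-spot intensity measurements.
#'
#' @param path CSV file with a header row.
#' @param dt frame interval in hours.
#' @return A [track_set()].
#' @export
read_track_table <- function(path, dt) {
  check_positive(dt, "dt")
  if (!file.exists(path)) stopf("cannot read track table: no such file '%s'", path)
  df <- read.csv(path, check.names = FALSE)
  nms <- names(df)
  i_track <- find_column(nms, c("^track.id$", "^track$", "track.id", "track"),
                         "the track id")
  i_frame <- find_column(nms, c("^frame$", "frame", "^t$"), "the frame")
  i_x <- find_column(nms, c("^x$", "position.x", "\\.x$"), "x (um)")
  i_y <- find_column(nms, c("^y$", "position.y", "\\.y$"), "y (um)")
  i_z <- find_column(nms, c("^z$", "position.z", "\\.z$"), "z (um)")
  out <- data.frame(track = df[[i_track]], frame = as.integer(df[[i_frame]]),
                    x = as.numeric(df[[i_x]]), y = as.numeric(df[[i_y]]),
                    z = as.numeric(df[[i_z]]))
  used <- c(i_track, i_frame, i_x, i_y, i_z)
  inten <- setdiff(grep("intensity|mean", tolower(nms)), used)
  for (j in inten) out[[nms[j]]] <- as.numeric(df[[j]])
  track_set(out, dt)
}

#' Default run configuration
#'
#' Flat list of every tunable the fusion and quantification pipeline uses.
#' Values not supplied keep their defaults; unknown names are rejected so a
#' typo in a config file fails loudly rather than being silently ignored.
#'
#' @param ... named overrides of the defaults listed below.
#' @return A validated named list of class `RunConfig`.
#'
#' @details Defaults:
#' \describe{
#'   \item{spacing_z, spacing_y, spacing_x}{voxel size in micrometres (1, 1, 1).}
#'   \item{sigmoid_slope}{sigmoid steepness of the view blend, in planes (3).}
#'   \item{dct_support_fraction}{radial fraction of DCT coefficients scored (1.0).}
#'   \item{dcts_norm}{"power" or "l2" normalization of the DCT spectrum.}
#'   \item{smoothing_window}{odd moving-average window for quality profiles (5).}
#'   \item{background}{constant camera offset in counts (0), or "auto" for the
#'     1st percentile of the input stacks.}
#'   \item{flip_axes}{axes mirrored on view 2 before registration ("z").}
#'   \item{register}{"once", "per_timepoint" or "off".}
#'   \item{register_metric}{"ncc" (normalized cross-correlation) or "mi"
#'     (mutual information).}
#'   \item{register_bins}{histogram bins for mutual information (32).}
#'   \item{register_maxit}{Nelder-Mead iteration cap per pyramid level (400).}
#'   \item{stitch_overlap_threshold}{IoU needed to link 2D masks across planes (0.25).}
#'   \item{volume_min, volume_max, axis_min, axis_max}{segmentation filter
#'     bounds (um^3 / um); unset by default and required for filtering.}
#'   \item{seed}{integer seed for the synthetic generators (NULL).}
#' }
#' @export
run_config <- function(...) {
  cfg <- list(
    spacing_z = 1, spacing_y = 1, spacing_x = 1,
    sigmoid_slope = 3, dct_support_fraction = 1.0, dcts_norm = "power",
    smoothing_window = 5L, background = 0, flip_axes = "z",
    register = "once", register_metric = "ncc", register_bins = 32L,
    register_maxit = 400L,
    stitch_overlap_threshold = 0.25,
    volume_min = NULL, volume_max = NULL, axis_min = NULL, axis_max = NULL,
    seed = NULL)
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(names(over) == "")))
    stopf("all config values must be named")
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stopf("unknown config keys: %s", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(cfg)
}

validate_config <- function(cfg) {
  check_positive(cfg$sigmoid_slope, "sigmoid_slope")
  if (!is.numeric(cfg$dct_support_fraction) ||
      cfg$dct_support_fraction <= 0 || cfg$dct_support_fraction > 1)
    stopf("dct_support_fraction must be in (0, 1]")
  cfg$smoothing_window <- as.integer(cfg$smoothing_window)
  if (cfg$smoothing_window < 1L || cfg$smoothing_window %% 2L != 1L)
    stopf("smoothing_window must be odd and >= 1")
  if (!identical(cfg$background, "auto")) {
    if (!is.numeric(cfg$background) || cfg$background < 0)
      stopf("background must be >= 0 counts or \"auto\"")
  }
  cfg$dcts_norm <- match.arg(cfg$dcts_norm, c("power", "l2"))
  cfg$register <- match.arg(cfg$register, c("once", "per_timepoint", "off"))
  cfg$register_metric <- match.arg(cfg$register_metric, c("ncc", "mi"))
  if (!all(cfg$flip_axes %in% c("z", "x")))
    stopf("flip_axes must be a subset of {z, x}")
  if (cfg$stitch_overlap_threshold < 0 || cfg$stitch_overlap_threshold > 1)
    stopf("stitch_overlap_threshold must be in [0, 1]")
  check_positive(c(cfg$spacing_z, cfg$spacing_y, cfg$spacing_x), "spacing")
  for (b in c("volume", "axis")) {
    lo <- cfg[[paste0(b, "_min")]]; hi <- cfg[[paste0(b, "_max")]]
    if (!is.null(lo) && !is.null(hi) && lo > hi)
      stopf("%s bounds are inverted (min > max)", b)
  }
  structure(cfg, class = "RunConfig")
}

#' Read a run configuration from a YAML-style key: value file
#'
#' @param path text file of `key: value` lines (flat YAML).
#' @return A `RunConfig`; unknown keys raise an error.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("cannot read config: no such file '%s'", path)
  vals <- read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(run_config, vals)
}

config_spacing <- function(cfg)
  c(cfg$spacing_z, cfg$spacing_y, cfg$spacing_x)
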