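#' Construct a set of 3D cell tracks
#'
#' @param spots data.frame with columns `track` (id), `frame` (integer),
#'   `x`, `y`, `z` (micrometres); additional columns (e.g. per-channel mean
#'   intensities) are carried along.
#' @param dt frame interval in hours.
#' @return An object of class `TrackSet`; rows are ordered by track then
#'   frame, and `n_tracks` equals the number of distinct track ids.
#' @export
track_set <- function(spots, dt) {
  check_positive(dt, "dt")
  need <- c("track", "frame", "x", "y", "z")
  miss <- setdiff(need, names(spots))
  if (length(miss))
    stopf("track table is missing column(s): %s", paste(miss, collapse = ", "))
  if (!all(is.finite(as.matrix(spots[, c("x", "y", "z")]))))
    stopf("positions must be finite")
  spots <- spots[order(spots$track, spots$frame), , drop = FALSE]
  dup <- duplicated(spots[, c("track", "frame")])
  if (any(dup))
    stopf("duplicate (track, frame) rows: e.g. track %s frame %s",
          spots$track[dup][1], spots$frame[dup][1])
  rownames(spots) <- NULL
  structure(list(spots = spots, dt = dt,
                 n_tracks = length(unique(spots$track))),
            class = "TrackSet")
}

#' @export
print.TrackSet <- function(x, ...) {
  cat(sprintf("TrackSet: %d tracks, %d spots, dt = %g h\n",
              x$n_tracks, nrow(x$spots), x$dt))
  invisible(x)
}

as_track_set <- function(x) {
  if (!inherits(x, "TrackSet")) stopf("expected a TrackSet")
  x
}

#' Ensemble 3D mean square displacement
#'
#' `msd3d(t) = (1/N) sum_i (r_i(t) - r_i(0))^2`, the ensemble average of
#' each cell's squared displacement from its own initial position. The
#' origin-anchored form is used as stated - no sliding-window time
#' averaging. Lags are counted per track from its first observed frame;
#' tracks contribute only at lags they cover, and the number of tracks
#' entering each average is reported.
#'
#' @param tracks a [track_set()].
#' @return An `MSDCurve` data.frame with columns `lag` (hours), `msd`
#'   (um^2) and `n` (tracks averaged at that lag); `msd` is 0 at lag 0.
#' @examples
#' ts <- simulate_tracks("ballistic", n_tracks = 1, n_steps = 5, dt = 1,
#'                       v = 2, seed = 1)
#' msd3d(ts)  # 4 t^2
#' @export
msd3d <- function(tracks) {
  tracks <- as_track_set(tracks)
  s <- tracks$spots
  if (!nrow(s)) stopf("empty TrackSet")
  parts <- lapply(split(s, s$track), function(tr) {
    data.frame(lag = tr$frame - tr$frame[1],
               disp2 = (tr$x - tr$x[1])^2 + (tr$y - tr$y[1])^2 +
                 (tr$z - tr$z[1])^2)
  })
  all_disp <- do.call(rbind, parts)
  agg <- tapply(all_disp$disp2, all_disp$lag, mean)
  n <- tapply(all_disp$disp2, all_disp$lag, length)
  lags <- as.integer(names(agg))
  out <- data.frame(lag = lags * tracks$dt, msd = as.numeric(agg),
                    n = as.integer(n))
  out <- out[order(out$lag), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("MSDCurve", "data.frame")
  out
}

#' Per-step migration speeds
#'
#' For each consecutive pair of observations within a track, the Euclidean
#' displacement divided by the elapsed time (gaps in the frame numbering
#' use the actual elapsed time). Tracks with a single spot contribute no
#' rows.
#'
#' @param tracks a [track_set()].
#' @return data.frame with columns `track`, `frame` (of the step's end) and
#'   `speed` (um/h).
#' @export
step_speeds <- function(tracks) {
  tracks <- as_track_set(tracks)
  s <- tracks$spots
  out <- lapply(split(s, s$track), function(tr) {
    if (nrow(tr) < 2L) return(NULL)
    i <- 2:nrow(tr)
    disp <- sqrt(diff(tr$x)^2 + diff(tr$y)^2 + diff(tr$z)^2)
    data.frame(track = tr$track[i], frame = tr$frame[i],
               speed = disp / (diff(tr$frame) * tracks$dt))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(track = character(), frame = integer(),
                      speed = numeric())
  rownames(out) <- NULL
  out
}

#' Mean speed per track
#'
#' @param tracks a [track_set()].
#' @return data.frame with one row per track: `track`, `mean_speed` (um/h),
#'   `n_steps`.
#' @export
track_speeds <- function(tracks) {
  st <- step_speeds(tracks)
  if (!nrow(st))
    return(data.frame(track = character(), mean_speed = numeric(),
                      n_steps = integer()))
  agg <- tapply(st$speed, st$track, mean)
  n <- tapply(st$speed, st$track, length)
  data.frame(track = names(agg), mean_speed = as.numeric(agg),
             n_steps = as.integer(n), row.names = NULL)
}

#' Total path length of one track
#'
#' Sum of consecutive Euclidean displacements; a single-point track has
#' length 0. By the triangle inequality the path length is never smaller
#' than the net displacement.
#'
#' @param positions n x 3 matrix (or data.frame) of positions in
#'   micrometres, in temporal order.
#' @return Path length in micrometres.
#' @export
path_length <- function(positions) {
  p <- as.matrix(positions)
  if (!nrow(p)) stopf("need at least one position")
  if (!all(is.finite(p))) stopf("positions must be finite")
  if (nrow(p) == 1L) return(0)
  sum(sqrt(rowSums(diff(p)^2)))
}

#' Path length of every track in a set
#'
#' @param tracks a [track_set()].
#' @return data.frame with columns `track` and `length` (um).
#' @export
track_lengths <- function(tracks) {
  tracks <- as_track_set(tracks)
  s <- tracks$spots
  len <- vapply(split(s, s$track),
                function(tr) path_length(tr[, c("x", "y", "z")]),
                numeric(1))
  data.frame(track = names(len), length = as.numeric(len), row.names = NULL)
}
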