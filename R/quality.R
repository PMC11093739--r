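## Orthonormal type-II DCT matrices, cached per size.
.dct_cache <- new.env(parent = emptyenv())

dct_matrix <- function(n) {
  key <- as.character(n)
  if (!is.null(.dct_cache[[key]])) return(.dct_cache[[key]])
  k <- 0:(n - 1L)
  D <- sqrt(2 / n) * cos(pi * outer(k, (2 * k + 1) / (2 * n)))
  D[1L, ] <- sqrt(1 / n)
  .dct_cache[[key]] <- D
  D
}

#' Focus score of one plane: Shannon entropy of the normalized DCT
#'
#' Sharp, high-frequency content spreads power across many DCT coefficients
#' and yields high spectral entropy; defocus blur concentrates power at low
#' frequencies and lowers it. The score is invariant to multiplying the
#' image by a positive constant and bounded by `log(K)` where `K` is the
#' number of retained coefficients.
#'
#' @param plane 2D numeric matrix, at least 4 x 4, all finite.
#' @param support_fraction fraction in (0, 1] of the DCT radial support
#'   retained: coefficients with index radius `> support_fraction *
#'   sqrt(H^2 + W^2)` are discarded before normalization.
#' @param subtract_mean subtract the plane mean before the transform so the
#'   score reflects structure, not offset (default `TRUE`).
#' @param norm `"power"` normalizes squared coefficients to a probability
#'   distribution; `"l2"` uses magnitudes over the L2 norm.
#' @return A single non-negative focus score (natural-log entropy); a plane
#'   that is constant (zero after mean subtraction) scores 0.
#' @examples
#' dcts_plane(matrix(rnorm(64 * 64), 64, 64))
#' dcts_plane(matrix(5, 16, 16))  # constant -> 0
#' @export
dcts_plane <- function(plane, support_fraction = 1, subtract_mean = TRUE,
                       norm = c("power", "l2")) {
  norm <- match.arg(norm)
  if (!is.matrix(plane) || nrow(plane) < 4L || ncol(plane) < 4L)
    stopf("plane must be a matrix of at least 4 x 4")
  if (!all(is.finite(plane))) stopf("plane contains non-finite pixels")
  if (support_fraction <= 0 || support_fraction > 1)
    stopf("support_fraction must be in (0, 1]")
  if (subtract_mean) plane <- plane - mean(plane)
  h <- nrow(plane); w <- ncol(plane)
  C <- dct_matrix(h) %*% plane %*% t(dct_matrix(w))
  if (support_fraction < 1) {
    r2 <- (support_fraction * sqrt(h^2 + w^2))^2
    keep <- outer((0:(h - 1L))^2, (0:(w - 1L))^2, `+`) <= r2
    c2 <- C[keep]^2
  } else {
    c2 <- as.vector(C)^2
  }
  tot <- sum(c2)
  if (tot == 0) return(0)
  p <- if (norm == "power") c2 / tot else sqrt(c2 / tot)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Per-plane focus profile of a stack
#'
#' Applies [dcts_plane()] to every z-plane, then smooths with a centered
#' moving average (edges shrink to fit); `smoothing_window = 1` disables
#' smoothing.
#'
#' @param stack a [volume_stack()].
#' @param support_fraction,subtract_mean,norm passed to [dcts_plane()].
#' @param smoothing_window odd integer, at most the plane count.
#' @return A `QualityProfile`: list with `scores` (one per plane, smoothed),
#'   `raw` (unsmoothed), `view_id`, `smoothing_window`.
#' @export
quality_profile <- function(stack, support_fraction = 1,
                            smoothing_window = 5L, subtract_mean = TRUE,
                            norm = "power") {
  stack <- as_volume(stack)
  nz <- dim(stack$data)[1]
  smoothing_window <- as.integer(smoothing_window)
  if (smoothing_window > nz)
    stopf("smoothing_window (%d) exceeds plane count (%d)",
          smoothing_window, nz)
  raw <- vapply(seq_len(nz), function(z) {
    tryCatch(dcts_plane(stack$data[z, , ], support_fraction,
                        subtract_mean, norm),
             error = function(e)
               stopf("plane %d: %s", z - 1L, conditionMessage(e)))
  }, numeric(1))
  structure(list(scores = moving_average(raw, smoothing_window), raw = raw,
                 view_id = stack$view_id,
                 smoothing_window = smoothing_window),
            class = "QualityProfile")
}

#' @export
print.QualityProfile <- function(x, ...) {
  cat(sprintf("QualityProfile [%s]: %d planes, window %d, score range [%.4g, %.4g]\n",
              x$view_id, length(x$scores), x$smoothing_window,
              min(x$scores), max(x$scores)))
  invisible(x)
}
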