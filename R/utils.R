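`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stopf("'%s' must be positive and finite", name)
  invisible(x)
}

## Evaluate `expr` under a fixed RNG state without disturbing the caller's
## stream; `seed = NULL` leaves the global stream in charge.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

## Centered moving average with shrink-to-fit edges; window must be odd.
moving_average <- function(x, window) {
  if (window %% 2L != 1L || window < 1L)
    stopf("smoothing window must be an odd integer >= 1, got %s", window)
  if (window == 1L) return(x)
  n <- length(x)
  h <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}

## Mean-pool a 3D array by integer factor f along every axis (remainder
## voxels cropped). Used for the registration pyramid.
pool3 <- function(a, f) {
  if (f == 1L) return(a)
  pool1 <- function(x) {
    d <- dim(x)
    n2 <- d[1L] %/% f
    x <- x[seq_len(n2 * f), , , drop = FALSE]
    dim(x) <- c(f, n2, d[2L], d[3L])
    colMeans(x)
  }
  ## pool axis 1, rotate axes, three times round brings axes back in order
  for (i in 1:3) a <- aperm(pool1(a), c(2, 3, 1))
  a
}
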