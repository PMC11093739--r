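## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths: the DCT oracle is a direct O(N^4) summation,
## the connected-components oracle is a plain BFS flood fill, the moment
## oracle sums voxel coordinates directly.

## Direct-summation orthonormal type-II DCT entropy (power normalization).
oracle_dcts <- function(img, subtract_mean = FALSE) {
  if (subtract_mean) img <- img - mean(img)
  H <- nrow(img); W <- ncol(img)
  scale_h <- c(sqrt(1 / H), rep(sqrt(2 / H), H - 1))
  scale_w <- c(sqrt(1 / W), rep(sqrt(2 / W), W - 1))
  C <- matrix(0, H, W)
  for (k in 0:(H - 1)) for (l in 0:(W - 1)) {
    s <- 0
    for (n in 0:(H - 1)) for (m in 0:(W - 1))
      s <- s + img[n + 1, m + 1] *
        cos(pi * (2 * n + 1) * k / (2 * H)) *
        cos(pi * (2 * m + 1) * l / (2 * W))
    C[k + 1, l + 1] <- scale_h[k + 1] * scale_w[l + 1] * s
  }
  p <- C^2 / sum(C^2)
  p <- p[p > 0]
  -sum(p * log(p))
}

## Number of 6-connected 3D components among nonzero voxels.
oracle_n_components_3d <- function(mask) {
  d <- dim(mask)
  seen <- array(FALSE, d)
  ncomp <- 0L
  idx <- which(mask > 0)
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))
  for (start in idx) {
    zi <- (start - 1) %% d[1] + 1
    yi <- ((start - 1) %/% d[1]) %% d[2] + 1
    xi <- (start - 1) %/% (d[1] * d[2]) + 1
    if (seen[zi, yi, xi]) next
    ncomp <- ncomp + 1L
    queue <- matrix(c(zi, yi, xi), 1)
    seen[zi, yi, xi] <- TRUE
    while (nrow(queue)) {
      cur <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (s in seq_len(nrow(shifts))) {
        nb <- cur + shifts[s, ]
        if (any(nb < 1) || any(nb > d)) next
        if (mask[nb[1], nb[2], nb[3]] > 0 && !seen[nb[1], nb[2], nb[3]]) {
          seen[nb[1], nb[2], nb[3]] <- TRUE
          queue <- rbind(queue, nb)
        }
      }
    }
  }
  ncomp
}

## Axis ratio from direct voxel-coordinate moment summation (no package
## code): eigenvalue ratio of the spacing-weighted covariance of voxel
## centres, with the voxel self-moment term.
oracle_axis_ratio <- function(mask, spacing = c(1, 1, 1)) {
  idx <- which(mask > 0, arr.ind = TRUE)
  phys <- sweep(idx - 1, 2, spacing, `*`)
  cc <- sweep(phys, 2, colMeans(phys))
  cov <- crossprod(cc) / nrow(cc) + diag(spacing^2 / 12)
  ev <- sort(eigen(cov, symmetric = TRUE)$values, decreasing = TRUE)
  sqrt(ev[1] / ev[3])
}

## Small stack of seeded white noise planes blurred progressively in z.
progressive_blur_stack <- function(nz = 10, side = 64, seed = 1,
                                   max_sigma = 4) {
  base <- duofuse:::with_seed(seed, matrix(rnorm(side * side), side, side))
  a <- array(0, c(nz, side, side))
  sig <- seq(0, max_sigma, length.out = nz)
  for (z in seq_len(nz)) {
    a[z, , ] <- if (sig[z] < 0.05) base else
      as.matrix(EBImage::gblur(base, sigma = sig[z], boundary = "replicate"))
  }
  volume_stack(a + 10, spacing = c(1, 1, 1))  # offset keeps counts positive
}
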