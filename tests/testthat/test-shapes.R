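test_that("stitching links masks by IoU and matches the 3D component oracle", {
  ## identical disk through 10 planes -> one label
  disk <- matrix(0L, 32, 32)
  disk[(row(disk) - 16)^2 + (col(disk) - 16)^2 <= 64] <- 1L
  st <- stitch_planes(replicate(10, disk, simplify = FALSE), 0.25)
  expect_equal(length(setdiff(unique(as.vector(st$labels)), 0L)), 1L)

  ## two never-overlapping disks -> two labels
  d2 <- matrix(0L, 32, 32)
  d2[(row(d2) - 8)^2 + (col(d2) - 8)^2 <= 16] <- 1L
  d3 <- matrix(0L, 32, 32)
  d3[(row(d3) - 24)^2 + (col(d3) - 24)^2 <= 16] <- 2L
  st2 <- stitch_planes(list(d2, d3, d2, d3), 0.25)
  ## planes alternate, so the disks never overlap between z and z+1
  expect_equal(length(setdiff(unique(as.vector(st2$labels)), 0L)), 4L)

  ## voxelized spheres, per-plane ids scrambled: label count equals the
  ## 3D connected-component count from the flood-fill oracle
  ## half-integer z centres: no degenerate single-voxel polar-cap planes
  lv <- ellipsoid_labels(c(30, 48, 48),
                         centers = list(c(14.5, 14, 14), c(14.5, 34, 34)),
                         semi_axes = list(c(9, 9, 9), c(7, 7, 7)))
  planes <- lapply(seq_len(30), function(z) {
    p <- lv$labels[z, , ]
    p[p > 0] <- ((p[p > 0] + z) %% 3) + 1L  # arbitrary per-plane ids
    p
  })
  st3 <- stitch_planes(planes, 0.25)
  n_found <- length(setdiff(unique(as.vector(st3$labels)), 0L))
  expect_equal(n_found, oracle_n_components_3d(lv$labels))
  expect_equal(n_found, 2L)
  ## labels are consecutive from 1
  expect_setequal(setdiff(unique(as.vector(st3$labels)), 0L), 1:2)

  expect_error(stitch_planes(list(disk, matrix(0L, 16, 16))), "same shape")
  expect_error(stitch_planes(list(disk), overlap_threshold = 2), "0, 1")
})

test_that("region features match analytic ellipsoid moments", {
  lv <- ellipsoid_labels(c(40, 40, 40), list(c(19.5, 19.5, 19.5)),
                         list(c(10, 5, 5)))
  f <- region_features(lv)
  expect_equal(nrow(f), 1L)
  expect_equal(f$axis_ratio, 2, tolerance = 0.05)
  expect_equal(f$major_axis, 20, tolerance = 0.05 * 20)
  expect_equal(f$minor_axis, 10, tolerance = 0.05 * 10)
  expect_equal(f$volume, 4 / 3 * pi * 10 * 5 * 5, tolerance = 0.05)
  ## direct moment-summation oracle
  expect_equal(f$axis_ratio, oracle_axis_ratio(lv$labels), tolerance = 1e-10)

  cube <- array(0L, c(20, 20, 20))
  cube[5:15, 5:15, 5:15] <- 1L
  fc <- region_features(label_volume(cube))
  expect_equal(fc$axis_ratio, 1, tolerance = 0.05)

  ## anisotropic spacing folds into the physical moments: the same voxel
  ## ellipsoid stretched 2x along z doubles its physical elongation
  lv2 <- ellipsoid_labels(c(40, 40, 40), list(c(39, 19.5, 19.5)),
                          list(c(20, 5, 5)), spacing = c(2, 1, 1))
  f2 <- region_features(lv2)
  expect_equal(f2$axis_ratio, 4, tolerance = 0.05 * 4)
  expect_equal(f2$axis_ratio, oracle_axis_ratio(lv2$labels, c(2, 1, 1)),
               tolerance = 1e-10)

  empty <- region_features(label_volume(array(0L, c(4, 4, 4))))
  expect_equal(nrow(empty), 0L)
})

test_that("region filtering agrees with a brute-force row scan", {
  feats <- data.frame(label = 1:5, volume = c(10, 100, 500, 900, 2000),
                      major_axis = c(2, 6, 10, 14, 30),
                      minor_axis = c(1, 4, 6, 8, 12),
                      axis_ratio = c(2, 1.5, 1.67, 1.75, 2.5))
  class(feats) <- c("RegionFeatures", "data.frame")
  out <- filter_regions(feats, volume = c(50, 1000), axis = c(0, Inf))
  expect_equal(out$label, 2:4)
  expect_equal(attr(out, "n_dropped"), 2L)

  ## keep-everything bounds are the identity
  all_out <- filter_regions(feats)
  expect_equal(all_out$label, feats$label)

  ## randomized tables vs brute force, plus idempotence
  for (seed in 1:10) {
    tab <- duofuse:::with_seed(seed, {
      n <- 30
      mn <- runif(n, 0.5, 10)
      data.frame(label = 1:n, volume = runif(n, 1, 3000),
                 major_axis = mn * runif(n, 1, 4), minor_axis = mn,
                 axis_ratio = runif(n, 1, 4))
    })
    vb <- c(100, 2000); ab <- c(1, 20)
    got <- filter_regions(tab, volume = vb, axis = ab)
    keep <- logical(nrow(tab))
    for (i in seq_len(nrow(tab)))
      keep[i] <- tab$volume[i] >= vb[1] && tab$volume[i] <= vb[2] &&
        tab$major_axis[i] >= ab[1] && tab$major_axis[i] <= ab[2] &&
        tab$minor_axis[i] >= ab[1] && tab$minor_axis[i] <= ab[2]
    expect_equal(got$label, tab$label[keep])
    twice <- filter_regions(got, volume = vb, axis = ab)
    expect_equal(twice$label, got$label)
  }
  expect_error(filter_regions(feats, volume = c(10, 1)), "inverted")
})
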