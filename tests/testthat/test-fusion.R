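test_that("opposing-view flips are involutions with exact index mapping", {
  v <- volume_stack(array(seq_len(6 * 5 * 4), c(6, 5, 4)))
  expect_equal(flip_opposing_view(flip_opposing_view(v, "z"), "z")$data,
               v$data)
  expect_equal(flip_opposing_view(v, character(0))$data, v$data)
  f <- flip_opposing_view(v, "z")
  for (k in 1:6) expect_equal(f$data[k, , ], v$data[6 + 1 - k, , ])
  fx <- flip_opposing_view(v, c("z", "x"))
  expect_equal(fx$data[2, 3, 1], v$data[5, 3, 4])
  expect_error(flip_opposing_view(v, "y"), "subset")
})

test_that("rigid transforms compose, invert and round-trip", {
  tr <- rigid_transform(rotation = c(2, -1, 0.5),
                        translation = c(1.5, -2, 0.7),
                        center = c(10, 20, 20))
  id <- compose_transforms(tr, invert_transform(tr))
  expect_lt(max(abs(id$rotation)), 1e-6)
  expect_lt(max(abs(id$translation)), 1e-6)
  ## pure translation has zero angles and an exact matrix form
  t2 <- rigid_transform(translation = c(1, 2, 3))
  M <- transform_matrix(t2)
  expect_equal(M[1:3, 1:3], diag(3))
  expect_equal(M[1:3, 4], c(1, 2, 3))
})

test_that("resampling matches shift and composition oracles", {
  v <- blob_phantom(shape = c(16, 24, 24), n_blobs = 20, seed = 8)
  ## identity
  expect_equal(resample(v, rigid_transform())$data, v$data, tolerance = 1e-12)
  ## integer-voxel translation equals an array shift on the interior
  tr <- rigid_transform(translation = c(2, 0, -3))
  r <- resample(v, tr, background = 0)
  expect_equal(r$data[1:14, , 4:24], v$data[3:16, , 1:21], tolerance = 1e-12)
  ## two half-voxel steps vs one full voxel: trilinear interpolation is
  ## exact on multilinear intensity fields, so composition must agree there
  d <- c(16, 24, 24)
  ramp <- array(0, d)
  for (z in 1:16) for (y in 1:24)
    ramp[z, y, ] <- 2 * z + 3 * y + 5 * seq_len(24) + 0.1 * z * y
  vr <- volume_stack(ramp)
  h <- rigid_transform(translation = c(0.5, 0, 0))
  twice <- resample(resample(vr, h), h)$data
  once <- resample(vr, rigid_transform(translation = c(1, 0, 0)))$data
  ## exclude the last two planes: the inner resample fills its final plane
  ## with background, which the outer pass would propagate one plane down
  interior <- abs(twice[1:14, , ] - once[1:14, , ])
  expect_lt(max(interior) / diff(range(ramp)), 1e-3)
})

test_that("registration recovers identity, translations and rotations", {
  ph <- blob_phantom(shape = c(40, 56, 56), n_blobs = 50, seed = 3)
  self <- register_rigid(ph, ph)
  expect_lt(max(abs(self$translation / ph$spacing)), 0.05)
  expect_lt(max(abs(self$rotation)), 0.05)

  tr <- rigid_transform(translation = c(1.5, -2, 3))  # voxels (spacing 1)
  mov <- resample(ph, invert_transform(tr))
  est <- register_rigid(mov, ph)
  expect_lt(max(abs(est$translation - tr$translation)), 0.25)

  ctr <- (dim(ph$data) - 1) / 2
  rot <- rigid_transform(rotation = c(2, 0, 0), center = ctr)
  movr <- resample(ph, invert_transform(rot))
  estr <- register_rigid(movr, ph)
  expect_lt(max(abs(estr$rotation - c(2, 0, 0))), 0.2)

  expect_error(register_rigid(volume_stack(array(1, c(8, 8, 8))),
                              volume_stack(array(1, c(8, 8, 8)))),
               "constant")
})

test_that("switch plane detection follows the crossover contract", {
  expect_equal(find_switch_plane(c(3, 2, 1, 0), c(0, 1, 2, 3)), 2L)
  ## brute-force oracle: first plane where the opposing view wins.
  ## p1 strictly decreasing, p2 strictly increasing -> at most one crossover.
  for (seed in 1:10) {
    n <- 20
    p <- duofuse:::with_seed(seed, list(
      p1 = sort(runif(n, 1, 2), decreasing = TRUE),
      p2 = sort(runif(n, 0.8, 2.2))))
    got <- find_switch_plane(p$p1, p$p2)
    win2 <- which(p$p2 >= p$p1)
    oracle <- if (p$p1[1] <= p$p2[1]) 0L else
      if (length(win2)) win2[1] - 1L else n - 1L
    expect_equal(got, oracle)
  }
  expect_equal(find_switch_plane(c(5, 4, 3), c(1, 1, 1)), 2L)  # p1 dominant
  expect_equal(find_switch_plane(c(1, 1, 1), c(5, 4, 3)), 0L)  # p2 dominant
  expect_equal(find_switch_plane(c(2, 2), c(2, 2)), 0L)        # exact tie
  expect_error(find_switch_plane(1:3, 1:4), "length")
})

test_that("sigmoid weights are complementary and approach a step", {
  w <- sigmoid_weights(50, z_switch = 20, slope = 3)
  expect_equal(w$w2[21], 0.5)                       # plane index 20, 0-based
  expect_lt(max(abs(w$w1 + w$w2 - 1)), 1e-12)
  ws <- sigmoid_weights(50, 20, slope = 1e-3)
  step <- as.numeric((0:49) > 20)
  away <- setdiff(1:50, 21)
  expect_lt(max(abs(ws$w2[away] - step[away])), 1e-6)
  expect_error(sigmoid_weights(50, 20, slope = 0), "positive")
})

test_that("fusion blends by depth weight and subtracts the background", {
  c1 <- volume_stack(array(200, c(30, 8, 8)))
  plan <- fusion_plan(z_switch = 15, slope = 2, background = 50)
  fused <- fuse_stacks(c1, c1, plan)
  expect_equal(as.vector(fused$data), rep(150, length(fused$data)),
               tolerance = 1e-12)
  expect_equal(fused$view_id, "fused")

  v1 <- blob_phantom(c(40, 16, 16), n_blobs = 10, seed = 1)
  v2 <- blob_phantom(c(40, 16, 16), n_blobs = 10, seed = 2)
  plan2 <- fusion_plan(z_switch = 30, slope = 2, background = 0)
  f2 <- fuse_stacks(v1, v2, plan2)
  ## planes >= 10 slopes below the switch are pure view1
  dr <- diff(range(v1$data))
  expect_lt(max(abs(f2$data[1:5, , ] - v1$data[1:5, , ])) / dr, 1e-4)
  ## identical stacks, zero background: identity at any switch plane
  f3 <- fuse_stacks(v1, v1, fusion_plan(10, 3, 0))
  expect_equal(f3$data, v1$data)
  expect_error(fuse_stacks(v1, blob_phantom(c(40, 16, 18), 5, seed = 3),
                           plan2), "shapes differ")
  expect_error(fusion_plan(60, 3, 0, n_planes = 40), "plane count")
})

test_that("the aligned-pair pipeline reproduces its input and is deterministic", {
  truth <- blob_phantom(c(24, 32, 32), n_blobs = 30, seed = 5)
  pr <- dual_view_pair(truth, degradation_model(blur_sigma0 = 0, blur_rate = 0,
                                                attenuation_rate = 0,
                                                background = c(0, 0)))
  cfg <- run_config(register = "off", background = 0)
  res <- run_fusion_pipeline(pr$view1, pr$view2, cfg)
  expect_equal(res$fused$data, truth$data, tolerance = 1e-10)
  expect_equal(nrow(res$report), 1L)
  expect_true(all(c("z_switch", "tx", "rz") %in% names(res$report)))
  res_again <- run_fusion_pipeline(pr$view1, pr$view2, cfg)
  expect_identical(res$plan$z_switch, res_again$plan$z_switch)
  expect_identical(res$fused$data, res_again$fused$data)

  bad <- volume_stack(array(0, c(24, 30, 32)))
  expect_error(run_fusion_pipeline(pr$view1, bad, cfg), "shapes differ")
})

test_that("the full pipeline recovers switch plane and misalignment together", {
  truth <- blob_phantom(c(50, 64, 64), n_blobs = 80, seed = 11)
  ctr <- (dim(truth$data) - 1) / 2
  mis <- rigid_transform(rotation = c(0.8, 0, 0),
                         translation = c(1, -0.8, 0.6), center = ctr)
  pr <- dual_view_pair(truth, degradation_model(), misalignment = mis,
                       crossover = 20)
  res <- run_fusion_pipeline(pr$view1, pr$view2,
                             run_config(background = 100))
  expect_lte(abs(res$plan$z_switch - 20), 2)
  expect_lt(max(abs(res$plan$transform$translation - mis$translation)), 0.35)
  expect_lt(abs(res$plan$transform$rotation[1] - 0.8), 0.35)
})
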