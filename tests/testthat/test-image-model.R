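test_that("interpolation reproduces node values for every scheme", {
  v <- volume_image(array(as.double(1:27), c(3, 3, 3)))
  for (scheme in c("nearest", "linear", "cubic_bspline")) {
    expect_equal(interpolate(v, c(1, 2, 0), scheme), v$values[2, 3, 1],
                 tolerance = 1e-10)
    expect_equal(interpolate(v, c(0, 0, 0), scheme), v$values[1, 1, 1],
                 tolerance = 1e-10)
  }
  big <- noise_volume(4, c(12, 10, 9))
  idx <- as.matrix(expand.grid(0:11, 0:9, 0:8))
  expect_equal(interpolate(big, idx, "cubic_bspline"),
               as.numeric(big$values), tolerance = 1e-10)
})

test_that("linear interpolation preserves constants and is exact on ramps", {
  v <- volume_image(array(7.5, c(5, 5, 5)))
  set.seed(1)
  pts <- cbind(runif(20, 0, 4), runif(20, 0, 4), runif(20, 0, 4))
  expect_equal(interpolate(v, pts, "linear"), rep(7.5, 20))
  ramp <- volume_image(array(0:2, c(3, 1, 1)))
  expect_equal(interpolate(ramp, c(0.5, 0, 0), "linear"), 0.5)
  # affine intensity field reproduced inside the hull
  g <- as.matrix(expand.grid(0:5, 0:5, 0:5))
  aff <- volume_image(array(2 + 0.5 * g[, 1] - g[, 2] + 0.25 * g[, 3],
                            c(6, 6, 6)))
  expect_equal(interpolate(aff, pts / 4 * 3 + 1, "linear"),
               2 + 0.5 * (pts[, 1] / 4 * 3 + 1) - (pts[, 2] / 4 * 3 + 1) +
                 0.25 * (pts[, 3] / 4 * 3 + 1),
               tolerance = 1e-10)
})

test_that("out-of-domain points return the fill value; bad points error", {
  v <- volume_image(array(1, c(4, 4, 4)))
  expect_equal(interpolate(v, c(-1, 0, 0)), 0)
  expect_equal(interpolate(v, c(0, 0, 10), fill = -5), -5)
  expect_error(interpolate(v, c(NA, 0, 0)), "finite")
})

test_that("world/index geometry honors spacing, origin and direction", {
  R <- euler_to_matrix(c(0, 0, pi / 6))
  v <- volume_image(array(0, c(4, 4, 4)), spacing = c(0.5, 2, 1),
                    origin = c(10, -3, 2), direction = R)
  idx <- rbind(c(0, 0, 0), c(1, 2, 3), c(3.5, 0.25, 1))
  w <- index_to_world(v, idx)
  expect_equal(world_to_index(v, w), idx, tolerance = 1e-12)
  expect_equal(w[1, ], c(10, -3, 2))
})

test_that("resampling with identity is exact; a one-voxel shift moves indices", {
  v <- noise_volume(2, c(8, 8, 8), spacing = 0.5)
  for (scheme in c("nearest", "linear"))
    expect_identical(resample(v, NULL, v, scheme = scheme)$values, v$values)
  sh <- resample(v, rigid3(translation = c(0.5, 0, 0)), v, scheme = "nearest")
  expect_equal(sh$values[1:7, , ], v$values[2:8, , ])
  expect_equal(sh$values[8, , ], matrix(0, 8, 8)) # border filled
})

test_that("resample through T then its inverse approximates the original", {
  set.seed(5)
  smooth <- smooth_volume_fixture()
  t <- rigid3(c(0.05, -0.03, 0.08), c(0.6, -0.4, 0.3), grid_center(smooth))
  fwd <- resample(smooth, t, smooth)
  md <- histomri:::linear_md(t)
  Minv <- solve(md$M)
  t_inv <- affine3(Minv, as.numeric(-Minv %*% md$d), c(0, 0, 0))
  back <- resample(fwd, t_inv, smooth)
  core <- 6:15
  err <- mean(abs(back$values[core, core, core] -
                    smooth$values[core, core, core]))
  expect_lt(err, 0.05 * diff(range(smooth$values)))
})

test_that("realignment to the native first-slice plane is the identity", {
  v <- noise_volume(3, c(10, 10, 6))
  p0 <- as.numeric(index_to_world(v, c((10 - 1) / 2, (10 - 1) / 2, 0)))
  plane <- reference_plane(c(0, 0, 1), p0, cbind(c(1, 0, 0), c(0, 1, 0)))
  out <- realign_to_reference_plane(v, plane, out_shape = dim(v$values))
  expect_equal(out$values, v$values, tolerance = 1e-9)
  expect_equal(out$origin, v$origin, tolerance = 1e-12)
})

test_that("realignment is world-coordinate invariant under plane rotation", {
  v <- smooth_volume_fixture()
  ctr <- grid_center(v)
  plane <- reference_plane(c(0, 0, 1), c(ctr[1], ctr[2], 1),
                           cbind(c(1, 0, 0), c(0, 1, 0)))
  plane_rot <- reference_plane(c(0, 0, 1), c(ctr[1], ctr[2], 1),
                               cbind(c(0, 1, 0), c(-1, 0, 0)))
  a <- realign_to_reference_plane(v, plane, scheme = "linear")
  b <- realign_to_reference_plane(v, plane_rot, scheme = "linear")
  # a voxel at a given world point has the same value in both resamplings
  pts <- rbind(c(4, 4.5, 3), c(5.2, 4.1, 2.4))
  expect_equal(interpolate(a, pts), interpolate(b, pts), tolerance = 1e-6)
})

test_that("a reference plane outside the image domain is rejected", {
  v <- noise_volume(1, c(6, 6, 6))
  plane <- reference_plane(c(0, 0, 1), c(0, 0, 99))
  expect_error(realign_to_reference_plane(v, plane), "outside")
})

test_that("channel extraction returns per-channel images of correct content", {
  red <- array(0, c(4, 4, 3)); red[, , 1] <- 255
  gray <- array(rep(seq_len(16), 3), c(4, 4, 3))
  st <- section_stack(list(red, gray), pixel_size = 10, interval = 80,
                      units = "um")
  r <- extract_channel(st, "red")
  g <- extract_channel(st, "green")
  expect_true(all(r[[1]] == 255))
  expect_true(all(g[[1]] == 0))
  expect_identical(r[[2]], g[[2]]) # grayscale-replicated RGB
  expect_equal(st$pixel_size, 0.01) # um converted to mm
})

test_that("dice overlap behaves at the extremes", {
  a <- array(c(TRUE, TRUE, FALSE, FALSE), c(2, 2))
  expect_equal(dice_overlap(a, a), 1)
  expect_equal(dice_overlap(a, !a), 0)
})
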