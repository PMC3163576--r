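test_that("point application matches the closed forms", {
  p <- c(1, 0, 0)
  expect_equal(as.numeric(apply_transform(rigid3(), p)), p)
  expect_equal(as.numeric(apply_transform(rigid3(translation = c(1, 2, 3)),
                                          c(0, 0, 0))), c(1, 2, 3))
  expect_equal(as.numeric(apply_transform(rigid3(c(0, 0, pi / 2)), p)),
               c(0, 1, 0), tolerance = 1e-12)
  expect_equal(as.numeric(apply_transform(similarity3(scale = 2), c(1, 1, 1))),
               c(2, 2, 2))
  A <- affine3(matrix(c(2, 0, 0, 0, 3, 0, 0, 0, 0.5), 3, 3))
  expect_equal(as.numeric(apply_transform(A, c(1, 1, 1))), c(2, 3, 0.5))
})

test_that("rigid transforms preserve pairwise distances and angles", {
  set.seed(8)
  pts <- matrix(rnorm(30, sd = 5), 10, 3)
  t <- rigid3(c(0.4, -0.2, 0.9), c(3, -1, 2), c(1, 1, 1))
  q <- apply_transform(t, pts)
  expect_equal(as.numeric(dist(q)), as.numeric(dist(pts)),
               tolerance = 1e-9)
  s <- similarity3(c(0.4, -0.2, 0.9), c(3, -1, 2), c(1, 1, 1), scale = 1.7)
  qs <- apply_transform(s, pts)
  expect_equal(as.numeric(dist(qs)), 1.7 * as.numeric(dist(pts)),
               tolerance = 1e-9)
})

test_that("composition applies components in order and collapses linearly", {
  a <- affine3(matrix(c(2, 0.1, 0, -0.2, 3, 0, 0, 0.3, 0.5), 3, 3),
               c(1, 0, 0), c(0.5, 0.5, 0.5))
  b <- rigid3(c(0, 0, pi / 4), c(0, 1, 0), c(1, 1, 1))
  cc <- compose_transforms(a, b)
  set.seed(9)
  p <- matrix(rnorm(30), 10, 3)
  expect_equal(apply_transform(cc, p),
               apply_transform(b, apply_transform(a, p)), tolerance = 1e-12)
  collapsed <- compose_transforms(a, b, collapse = TRUE)
  expect_s3_class(collapsed, "affine3")
  expect_equal(apply_transform(collapsed, p), apply_transform(cc, p),
               tolerance = 1e-10)
  expect_equal(transform_determinant(collapsed),
               det(histomri:::linear_part(a)) * det(histomri:::linear_part(b)),
               tolerance = 1e-10)
  # two translations add
  t2 <- compose_transforms(rigid3(translation = c(1, 0, 0)),
                           rigid3(translation = c(0, 1, 0)), collapse = TRUE)
  expect_equal(as.numeric(apply_transform(t2, c(0, 0, 0))), c(1, 1, 0))
  # compose(identity, T) acts as T
  idT <- compose_transforms(rigid3(), b)
  expect_equal(apply_transform(idT, p), apply_transform(b, p))
})

test_that("Euler angles round-trip away from gimbal lock", {
  for (ang in list(c(3, -2, 1) * pi / 180, c(0.3, 0.5, -0.7),
                   c(-1.2, 0.9, 2.5))) {
    expect_equal(matrix_to_euler(euler_to_matrix(ang)), ang,
                 tolerance = 1e-9)
  }
  # gimbal lock: second angle 90 degrees, third angle set to 0 by convention
  g <- matrix_to_euler(euler_to_matrix(c(0.4, pi / 2, 0.3)))
  expect_equal(g[2], pi / 2, tolerance = 1e-9)
  expect_equal(g[3], 0)
  expect_equal(euler_to_matrix(g), euler_to_matrix(c(0.4, pi / 2, 0.3)),
               tolerance = 1e-9)
})

test_that("rotation angles and out-of-plane angulation report correctly", {
  expect_equal(rotation_angles_deg(rigid3()), c(0, 0, 0))
  t <- rigid3(c(3, -2, 1) * pi / 180)
  expect_equal(rotation_angles_deg(t), c(3, -2, 1), tolerance = 1e-9)
  # a 2.3 degree tilt about an in-plane axis is reported as 2.3 degrees
  expect_equal(out_of_plane_angulation(rigid3(c(2.3 * pi / 180, 0, 0))),
               2.3, tolerance = 1e-9)
  # pure in-plane rotation leaves the plane normal fixed
  expect_equal(out_of_plane_angulation(rigid3(c(0, 0, 10 * pi / 180))), 0,
               tolerance = 1e-9)
})

test_that("determinants follow the linear part", {
  expect_equal(transform_determinant(rigid3(c(0.2, 0.1, -0.3))), 1,
               tolerance = 1e-12)
  expect_equal(transform_determinant(similarity3(scale = 1.0422)),
               1.0422^3, tolerance = 1e-12)
  expect_equal(1.0422^3, 1.132, tolerance = 1e-3) # +13.2 percent volume
  expect_equal(transform_determinant(affine3(diag(c(2, 3, 0.5)))), 3)
})

test_that("B-spline displacement has the cubic kernel properties", {
  coef0 <- array(0, c(6, 6, 6, 3))
  bs0 <- bspline3(c(-2, -2, -2), c(2, 2, 2), coef0)
  set.seed(10)
  pts <- matrix(runif(30, 0, 4), 10, 3)
  expect_equal(bspline_displacement(bs0, pts), matrix(0, 10, 3))
  expect_equal(apply_transform(bs0, pts), pts)
  # partition of unity: constant coefficients displace by that constant
  bs1 <- bspline3(c(-2, -2, -2), c(2, 2, 2), array(1.5, c(6, 6, 6, 3)))
  expect_equal(bspline_displacement(bs1, pts),
               matrix(1.5, 10, 3), tolerance = 1e-12)
  # single unit coefficient at a control point: central weight (2/3)^3
  c1 <- coef0; c1[3, 3, 3, 1] <- 1
  bs2 <- bspline3(c(-2, -2, -2), c(2, 2, 2), c1)
  expect_equal(bspline_displacement(bs2, c(2, 2, 2))[1, 1], (2 / 3)^3,
               tolerance = 1e-12)
  # identity outside the control-grid support
  expect_equal(bspline_displacement(bs1, c(50, 50, 50)), matrix(0, 1, 3))
})

test_that("transform files round-trip losslessly, composites included", {
  dir <- withr::local_tempdir()
  t1 <- rigid3(c(pi / 7, -0.123456789012345, 2e-9), c(1 / 3, -2 / 7, 0.1),
               c(6.3, 6.3, 6.3))
  f1 <- file.path(dir, "t1.txt")
  write_transform(t1, f1)
  b1 <- read_transform(f1)
  expect_identical(b1$angles, t1$angles)
  expect_identical(b1$translation, t1$translation)
  s1 <- similarity3(c(0.1, 0.2, 0.3), c(1, 2, 3), scale = 0.95390625)
  expect_identical(read_transform(write_transform(
    s1, file.path(dir, "s.txt")))$scale, s1$scale)
  set.seed(11)
  bs <- bspline3(c(-4, -4, -4), c(4, 4, 4),
                 array(rnorm(5 * 5 * 5 * 3), c(5, 5, 5, 3)))
  comp <- composite_transform(bs, affine3(matrix(rnorm(9) / 10 + diag(3), 3, 3),
                                          c(0.1, 0.2, 0.3)))
  fc <- file.path(dir, "comp.txt")
  write_transform(comp, fc)
  back <- read_transform(fc)
  p <- matrix(rnorm(15), 5, 3)
  expect_identical(apply_transform(back, p), apply_transform(comp, p))
})

test_that("inversion is exact for linear transforms and accurate for B-splines", {
  t <- similarity3(c(0.2, -0.1, 0.4), c(1, -2, 0.5), c(3, 3, 3), 0.93)
  inv <- invert_transform(t)
  set.seed(12)
  p <- matrix(rnorm(30, sd = 3), 10, 3)
  expect_equal(inv(apply_transform(t, p)), p, tolerance = 1e-10)
  bs <- bspline3(c(-4, -4, -4), c(4, 4, 4),
                 array(rnorm(6 * 6 * 6 * 3, 0, 0.2), c(6, 6, 6, 3)))
  invb <- invert_transform(bs)
  q <- matrix(runif(30, 2, 8), 10, 3)
  expect_equal(apply_transform(bs, invb(q)), q, tolerance = 1e-6)
})
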