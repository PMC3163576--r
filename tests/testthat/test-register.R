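# single-stage registration recovery on small phantoms with known ground
# truth; the full three-stage strategy is exercised in test-acceptance.R

test_that("registering an image to itself stays at the identity", {
  ph <- shrink_phantom(1)
  fx <- ph$invivo
  cfg <- registration_config(seed = 7, iterations_per_level = 100)
  t <- register(fx, fx, "rigid", cfg)
  expect_lt(max(abs(t$translation)), 0.1 * min(fx$spacing))
  expect_lt(max(abs(rotation_angles_deg(t))), 0.1)
})

test_that("a pure translation is recovered within 0.2 voxel", {
  ph <- shrink_phantom(1)
  fx <- ph$invivo
  dt <- c(0.4, 0.2, 0) # 2, 1, 0 voxels
  mv <- resample(fx, rigid3(translation = -dt), fx)
  cfg <- registration_config(seed = 7, iterations_per_level = 150)
  t <- register(fx, mv, "rigid", cfg)
  expect_lt(max(abs(t$translation - dt)), 0.2 * fx$spacing[1])
})

test_that("an isotropic scale of 1.05 is recovered by the similarity model", {
  ph <- shrink_phantom(1)
  fx <- ph$invivo
  ctr <- grid_center(fx)
  mv <- resample(fx, similarity3(center = ctr, scale = 1.05), fx)
  cfg <- registration_config(seed = 7, iterations_per_level = 150)
  cfg$fixed_mask <- mask_dilate(ph$labels_invivo > 0, 3)
  t <- register(fx, mv, "similarity", cfg)
  # pull-back truth: the inverse scale
  expect_gt(t$scale, 1 / 1.055)
  expect_lt(t$scale, 1 / 1.045)
})

test_that("a known affine map is recovered entrywise within 2 percent", {
  ph <- shrink_phantom(1)
  fx <- ph$invivo
  ctr <- grid_center(fx)
  A <- affine3(matrix(c(1.04, 0.02, 0, -0.01, 0.97, 0.01, 0, 0.02, 1.02),
                      3, 3), c(0.3, -0.2, 0.1), ctr)
  mv <- resample(fx, A, fx)
  cfg <- registration_config(seed = 7, iterations_per_level = 150)
  t <- register(fx, mv, "affine", cfg)
  md <- histomri:::linear_md(t)
  Minv <- solve(A$matrix)
  d_true <- as.numeric(ctr - Minv %*% (ctr + A$translation))
  expect_lt(max(abs(md$M - Minv)), 0.02)
  expect_lt(max(abs(md$d - d_true)), 0.1)
})

test_that("a deliberately disjoint initialization raises an overlap error", {
  ph <- shrink_phantom(1)
  fx <- ph$invivo
  cfg <- registration_config(seed = 7, iterations_per_level = 10)
  cfg$fixed_mask <- ph$labels_invivo > 0
  far <- rigid3(translation = c(200, 200, 200))
  expect_error(register(fx, fx, "rigid", cfg, init = far),
               "overlap|inside")
})

test_that("a fixed seed makes registration bit-reproducible", {
  ph <- shrink_phantom(1)
  fx <- ph$invivo
  mv <- resample(fx, rigid3(translation = c(-0.3, 0.1, 0)), fx)
  cfg <- registration_config(seed = 99, iterations_per_level = 60)
  t1 <- register(fx, mv, "rigid", cfg)
  t2 <- register(fx, mv, "rigid", cfg)
  expect_identical(t1$angles, t2$angles)
  expect_identical(t1$translation, t2$translation)
})

test_that("the metric never gets worse than the initialization it was given", {
  ph <- shrink_phantom(2)
  fx <- ph$invivo
  mv <- resample(fx, rigid3(translation = c(-0.3, 0.2, 0.1)), fx)
  cfg <- registration_config(seed = 5, iterations_per_level = 40)
  t <- register(fx, mv, "rigid", cfg)
  expect_lte(attr(t, "metric_value"), attr(t, "metric_initial") + 1e-12)
})
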