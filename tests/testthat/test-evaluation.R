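test_that("landmark RMS follows its closed forms and symmetry", {
  a <- landmark_set(rbind(L1 = c(0, 0, 0), L2 = c(1, 1, 1)))
  expect_equal(landmark_rms(a, a), 0)
  b <- landmark_set(rbind(L1 = c(1, 0, 0), L2 = c(1, 2, 1)))
  expect_equal(landmark_rms(a, b), 1) # sqrt((1^2 + 1^2) / 2)
  expect_equal(landmark_rms(a, b), landmark_rms(b, a))
  one_a <- landmark_set(rbind(P = c(0, 0, 0)))
  one_b <- landmark_set(rbind(P = c(0, 0.7, 0)))
  expect_equal(interobserver_rms(one_a, one_b), 0.7)
  # mapping through a transform first
  t <- rigid3(translation = c(1, 0, 0))
  expect_equal(landmark_rms(a, b, t = t), sqrt((0 + 2) / 2))
  bad <- landmark_set(rbind(X = c(0, 0, 0), L2 = c(0, 0, 0)))
  expect_error(landmark_rms(a, bad), "L1")
})

test_that("interobserver RMS recovers a known jitter magnitude", {
  set.seed(31)
  pts <- matrix(rnorm(30, sd = 4), 10, 3)
  rownames(pts) <- sprintf("L%02d", 1:10)
  jit <- matrix(rnorm(30, sd = 0.5), 10, 3)
  o1 <- landmark_set(pts, observer = "one")
  o2 <- landmark_set(pts + jit, observer = "two")
  expect_equal(interobserver_rms(o1, o2), sqrt(mean(rowSums(jit^2))))
  expect_lt(abs(interobserver_rms(o1, o2) - sqrt(3) * 0.5), 0.35)
})

test_that("the relative volume-change formula is exact", {
  expect_equal(volume_change_percent(1000, 1000), 0)
  expect_equal(volume_change_percent(1000, 868), -13.2)
  for (x in c(-50, -13.2, -1.9, 0, 13.2, 50))
    expect_equal(volume_change_percent(100, 100 * (1 + x / 100)), x,
                 tolerance = 1e-12)
  expect_error(volume_change_percent(0, 10), "positive")
})

test_that("global volume change reads the stage determinant", {
  expect_equal(global_volume_change(affine3(diag(3))), 0)
  s <- similarity3(scale = 1.132^(1 / 3))
  expect_equal(global_volume_change(s), 13.2, tolerance = 1e-9)
})

test_that("warping a mask by an isotropic scale matches the determinant", {
  mask <- array(FALSE, c(40, 40, 40))
  g <- as.matrix(expand.grid(0:39, 0:39, 0:39))
  mask[rowSums((g - 19.5)^2) <= 13^2] <- TRUE
  vol <- volume_image(mask * 1.0, spacing = c(0.2, 0.2, 0.2))
  s <- 1.05
  t <- similarity3(center = grid_center(vol), scale = s) # pull-back
  w <- resample(vol, t, vol, scheme = "nearest")
  got <- volume_change_percent(voi_volume(mask, vol),
                               voi_volume(w$values > 0.5, vol))
  expect_equal(got, 100 * (1 / s^3 - 1), tolerance = 1.5)
})

test_that("intensity pdfs have unit mass and correct quartiles", {
  const <- volume_image(array(42, c(8, 8, 8)))
  p <- estimate_pdf(const)
  expect_equal(sum(p$probability), 1)
  expect_equal(unname(p$quartiles), c(42, 42, 42))
  set.seed(32)
  u <- volume_image(array(runif(40^3, 0, 100), c(40, 40, 40)))
  pu <- estimate_pdf(u)
  expect_equal(sum(pu$probability), 1)
  expect_lt(abs(pu$quartiles[["Q1"]] - 25), 2)
  expect_lt(abs(pu$quartiles[["Q3"]] - 75), 2)
  expect_error(estimate_pdf(u, array(FALSE, c(40, 40, 40))), "empty")
})

test_that("disjoint intensity ranges give non-overlapping pdf supports", {
  v <- array(0, c(10, 10, 2))
  m1 <- array(c(TRUE, FALSE), c(10, 10, 2))
  m2 <- !m1
  set.seed(33)
  v[m1] <- rnorm(sum(m1), 20, 2)
  v[m2] <- rnorm(sum(m2), 80, 2)
  p1 <- estimate_pdf(v, m1)
  p2 <- estimate_pdf(v, m2)
  expect_lt(p1$range[2], p2$range[1])
})

test_that("interquartile segmentation selects the closed interval", {
  v <- volume_image(array(as.double(1:100), c(10, 10, 1)))
  p <- estimate_pdf(v)
  seg <- interquartile_segment(v, p)
  expect_true(all(v$values[seg] >= p$quartiles[["Q1"]]))
  expect_true(all(v$values[seg] <= p$quartiles[["Q3"]]))
  # whole image below Q1 of another pdf: empty mask
  hi <- estimate_pdf(volume_image(array(rep(c(500, 600), 50), c(10, 10, 1))))
  expect_false(any(interquartile_segment(v, hi)))
  # domain restriction
  dom <- array(FALSE, c(10, 10, 1)); dom[1:3, , ] <- TRUE
  expect_true(all(which(interquartile_segment(v, p, dom)) %in% which(dom)))
})

test_that("a VOI's own interquartile range selects about half of it", {
  ph <- default_phantom(1)
  m <- phantom_masks(ph, "invivo")
  for (lab in c("viable", "necrotic", "hemorrhagic")) {
    p <- estimate_pdf(ph$invivo, m[[lab]])
    seg <- interquartile_segment(ph$invivo, p)
    frac <- sum(seg & m[[lab]]) / sum(m[[lab]])
    expect_lt(abs(frac - 0.5), max(p$probability) + 0.02)
  }
})

test_that("landmark files round-trip with observer and image tags", {
  dir <- withr::local_tempdir()
  pts <- matrix(c(1.25, -2.5, 3.75, 0.1, 0.2, 0.3), 2, 3, byrow = TRUE)
  rownames(pts) <- c("apex", "notch")
  lm <- landmark_set(pts, observer = "obs1", image = "invivo")
  f <- file.path(dir, "lm.txt")
  write_landmarks(lm, f)
  back <- read_landmarks(f)
  expect_identical(back$points, lm$points)
  expect_equal(back$observer, "obs1")
  expect_equal(back$image, "invivo")
})
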