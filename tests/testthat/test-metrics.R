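test_that("the hand-computed two-cluster joint histogram gives exactly 1 bit", {
  f <- volume_image(array(rep(c(0, 1), each = 8), c(4, 4, 1)))
  mi <- mutual_information(f, f)
  expect_equal(mi$mi, 1)
  expect_equal(mi$value, -1)
})

test_that("self mutual information equals the marginal entropy and is a local minimum", {
  set.seed(21)
  v <- volume_image(array(sample(0:7, 32 * 32, replace = TRUE), c(32, 32, 1)))
  mi <- mutual_information(v, v, cfg = registration_config(histogram_bins = 8))
  p <- tabulate(as.numeric(v$values) + 1, 8) / 1024
  H <- -sum(p * log2(p))
  expect_equal(mi$mi, H, tolerance = 1e-9)
  # small translations cannot improve the cost
  for (dt in list(c(0.3, 0, 0), c(0, -0.4, 0))) {
    shifted <- mutual_information(v, v, t = rigid3(translation = dt),
                                  cfg = registration_config(histogram_bins = 8))
    expect_gt(shifted$value, mi$value)
  }
})

test_that("mutual information of independent noise images is near zero", {
  set.seed(42)
  f <- volume_image(array(runif(128 * 128), c(128, 128, 1)))
  m <- volume_image(array(runif(128 * 128), c(128, 128, 1)))
  mi <- mutual_information(f, m)
  expect_lt(mi$mi, 0.05)
  expect_gte(mi$mi, 0)
})

test_that("mutual information matches an independent brute-force implementation", {
  g <- expand.grid(x = 0:63, y = 0:63)
  f <- matrix(100 * exp(-((g$x - 30)^2 + (g$y - 34)^2) / 300) +
                20 * sin(g$x / 5), 64, 64)
  m <- sqrt(abs(f)) * 12 + 5
  ours <- mutual_information(volume_image(array(f, c(64, 64, 1))),
                             volume_image(array(m, c(64, 64, 1))))$mi
  orc <- oracle_mi_pv(as.numeric(f), as.numeric(m))
  expect_equal(ours, orc, tolerance = 1e-10)
  # invariance under bijective relabeling of one image's bins
  perm <- matrix((max(m) + min(m)) - m, 64, 64) # reflection of intensities
  ours_p <- mutual_information(volume_image(array(f, c(64, 64, 1))),
                               volume_image(array(perm, c(64, 64, 1))))$mi
  expect_equal(ours_p, ours, tolerance = 0.02 * ours)
})

test_that("normalized correlation is invariant to affine intensity maps", {
  set.seed(22)
  f <- volume_image(array(runif(16^3), c(16, 16, 16)))
  m <- volume_image(2.5 * f$values + 7)
  expect_equal(normalized_correlation(f, f)$value, -1, tolerance = 1e-12)
  expect_equal(normalized_correlation(f, m)$value, -1, tolerance = 1e-12)
  neg <- volume_image(-3 * f$values + 1)
  expect_equal(normalized_correlation(f, neg)$value, -1, tolerance = 1e-12)
})

test_that("degenerate intensity configurations are rejected, not silently zero", {
  ramp <- volume_image(array(seq_len(64), c(4, 4, 4)))
  flat <- volume_image(array(5, c(4, 4, 4)))
  expect_error(normalized_correlation(ramp, flat), "variance")
  expect_error(mutual_information(flat, ramp), "distinct")
  cfg <- registration_config()
  cfg$fixed_mask <- array(FALSE, c(4, 4, 4))
  expect_error(mutual_information(ramp, ramp, cfg = cfg), "mask excludes")
})

test_that("the pyramid downsamples by the configured factors", {
  v <- noise_volume(23, c(64, 64, 64), spacing = 0.2)
  pyr <- build_pyramid(v, registration_config())
  expect_equal(vapply(pyr, function(x) dim(x$values)[1], 0L), c(16L, 32L, 64L))
  expect_equal(pyr[[1]]$spacing, rep(0.8, 3))
  expect_equal(pyr[[1]]$origin, v$origin) # node 0 kept
  # single-level pyramid is the original image
  one <- build_pyramid(v, registration_config(pyramid_factors = 1,
                                              pyramid_smooth = 0))
  expect_identical(one[[1]]$values, v$values)
  # constant image stays constant at every level
  cpyr <- build_pyramid(volume_image(array(3, c(32, 32, 32))),
                        registration_config())
  for (lv in cpyr) expect_equal(range(lv$values), c(3, 3), tolerance = 1e-9)
  # too-small image: levels skipped with a warning
  expect_warning(build_pyramid(noise_volume(1, c(8, 8, 8)),
                               registration_config()), "skipped")
})

test_that("sampled and exhaustive estimates agree as sampling grows", {
  set.seed(24)
  g <- expand.grid(x = 0:63, y = 0:63)
  f <- matrix(exp(-((g$x - 28)^2 + (g$y - 36)^2) / 200), 64, 64) * 90 +
    rnorm(4096, 0, 3)
  m <- matrix(exp(-((g$x - 28)^2 + (g$y - 36)^2) / 200), 64, 64) * 60 + 10 +
    rnorm(4096, 0, 3)
  fv <- volume_image(array(f, c(64, 64, 1)))
  mv <- volume_image(array(m, c(64, 64, 1)))
  cfg <- registration_config(histogram_bins = 16)
  full <- mutual_information(fv, mv, cfg = cfg)$mi
  set.seed(1)
  half <- mutual_information(fv, mv, cfg = cfg, samples = 3500)$mi
  expect_lt(abs(half - full) / full, 0.02)
})
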