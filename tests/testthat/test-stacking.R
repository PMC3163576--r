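make_uniform_stack <- function(n = 4, shape = c(40, 40)) {
  img <- array(0, c(shape, 3))
  img[, , 1] <- matrix(120 + outer(sin(seq_len(shape[1]) / 3),
                                   cos(seq_len(shape[2]) / 4)) * 40,
                       shape[1], shape[2])
  img[, , 2] <- img[, , 1] * 0.6
  img[, , 3] <- img[, , 1] * 0.8
  section_stack(rep(list(img), n), pixel_size = 0.1, interval = 0.08)
}

test_that("identical sections stack with identity transforms", {
  st <- make_uniform_stack(4)
  sr <- stack_sections(st)
  for (t in sr$per_slice_transforms) {
    expect_lt(max(abs(t$translation)), 0.1 * 0.1) # < 0.1 px
    expect_lt(abs(t$angle), 0.1 * pi / 180)
  }
  # stacked volume constant along z (interior: border pixels may fall on
  # the domain edge under the near-identity transforms)
  v <- sr$channels$red$values
  expect_lt(max(abs(v[2:39, 2:39, 1] - v[2:39, 2:39, 4])), 0.01)
})

test_that("stack extent along z equals (n-1) times the interval", {
  st <- make_uniform_stack(6)
  sr <- stack_sections(st)
  d <- dim(sr$channels$red$values)
  expect_equal(d[3], 6L)
  expect_equal(sr$channels$red$spacing[3], 0.08)
  zmax <- max(grid_world_points(sr$channels$red)[, 3])
  expect_equal(zmax, (6 - 1) * 0.08)
})

test_that("stacking refuses a single section", {
  st <- make_uniform_stack(1)
  expect_error(stack_sections(st), ">= 2 sections")
})

test_that("known per-slice jitter on a noiseless phantom is recovered", {
  # small stack for speed; the full 30-section condition runs in the
  # acceptance suite
  ph <- jitter_only_phantom(1)
  sub <- section_stack(ph$sections$sections[1:8],
                       pixel_size = ph$sections$pixel_size,
                       interval = ph$sections$interval)
  sr <- stack_sections(sub)
  px <- ph$cfg$section_pixel_size
  errs <- t(sapply(1:8, function(k) {
    tr <- sr$per_slice_transforms[[k]]
    truth <- ph$truth$jitter[[k]]
    c(px = sqrt(sum((tr$translation - truth$translation)^2)) / px,
      deg = abs(tr$angle - truth$angle) * 180 / pi)
  }))
  expect_lt(mean(errs[, "px"]), 0.5)
  expect_lt(mean(errs[, "deg"]), 0.5)
})

test_that("channel selection maximizes constructed contrast and breaks ties to red", {
  shape <- c(30, 30)
  necro <- matrix(FALSE, shape[1], shape[2]); necro[5:12, 5:12] <- TRUE
  viab <- matrix(FALSE, shape[1], shape[2]); viab[18:26, 18:26] <- TRUE
  img <- array(100, c(shape, 3))
  set.seed(30)
  # classes differ only in the red channel
  img[, , 1][necro] <- 220 + rnorm(sum(necro), 0, 4)
  img[, , 1][viab] <- 90 + rnorm(sum(viab), 0, 4)
  img[, , 2] <- 100 + rnorm(prod(shape), 0, 4)
  img[, , 3] <- 100 + rnorm(prod(shape), 0, 4)
  st <- section_stack(list(img), pixel_size = 0.1, interval = 0.08)
  sel <- select_registration_channel(st, necro, viab)
  expect_equal(sel$channel, "red")
  expect_true(sel$scores["red"] > max(sel$scores[c("green", "blue")]))
  # all channels identical: tie broken toward red
  gray <- array(rep(img[, , 1], 3), c(shape, 3))
  st2 <- section_stack(list(gray), pixel_size = 0.1, interval = 0.08)
  sel2 <- select_registration_channel(st2, necro, viab)
  expect_equal(sel2$channel, "red")
  expect_error(select_registration_channel(st, necro & FALSE, viab),
               "empty VOI")
})

test_that("H&E-like phantom sections select the red channel", {
  ph <- default_phantom(1)
  k <- 15
  sel <- select_registration_channel(ph$sections,
                                     ph$section_labels[[k]] == 2L,
                                     ph$section_labels[[k]] == 1L,
                                     section = k)
  expect_equal(sel$channel, "red")
  expect_true(sel$scores["red"] > sel$scores["green"])
  expect_true(sel$scores["red"] > sel$scores["blue"])
})
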