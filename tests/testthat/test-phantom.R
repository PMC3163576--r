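test_that("generation is bit-reproducible under a fixed seed", {
  ph1 <- default_phantom(1)
  ph2 <- generate_phantom(phantom_config(seed = 1))
  expect_identical(ph1$invivo$values, ph2$invivo$values)
  expect_identical(ph1$exvivo$values, ph2$exvivo$values)
  expect_identical(ph1$sections$sections, ph2$sections$sections)
  expect_identical(ph1$landmarks_stack$points, ph2$landmarks_stack$points)
})

test_that("requested compartment fractions are realized within 0.03", {
  cfg <- phantom_config(seed = 3, fractions = c(viable = 0.55,
                                                necrotic = 0.30,
                                                hemorrhagic = 0.10))
  ph <- generate_invivo(cfg)
  m <- phantom_masks(ph, "invivo")
  nt <- sum(m$tumor)
  req <- cfg$fractions / sum(cfg$fractions)
  expect_lt(abs(sum(m$viable) / nt - req[["viable"]]), 0.03)
  expect_lt(abs(sum(m$necrotic) / nt - req[["necrotic"]]), 0.03)
  expect_lt(abs(sum(m$hemorrhagic) / nt - req[["hemorrhagic"]]), 0.03)
  # compartments are disjoint and fill the tumor
  expect_equal(sum(m$viable) + sum(m$necrotic) + sum(m$hemorrhagic), nt)
})

test_that("necrotic intensities are separated; viable and hemorrhagic overlap", {
  ph <- default_phantom(1)
  m <- phantom_masks(ph, "invivo")
  pn <- estimate_pdf(ph$invivo, m$necrotic)
  pv <- estimate_pdf(ph$invivo, m$viable)
  phm <- estimate_pdf(ph$invivo, m$hemorrhagic)
  expect_lt(pn$range[2], pv$range[1]) # separated supports
  expect_lt(pn$range[2], phm$range[1])
  # viable and hemorrhagic interquartile ranges overlap substantially
  expect_lt(phm$quartiles[["Q1"]], pv$quartiles[["Q3"]])
  expect_gt(phm$quartiles[["Q3"]], pv$quartiles[["Q1"]])
})

test_that("the programmed fixation shrinkage is realized by mask counting", {
  for (seed in 1:3) {
    ph <- shrink_phantom(seed)
    expect_lt(abs(ph$truth$volume_ratio - 0.868), 0.01)
  }
  # default (deformed) phantom too: the deformation is volume-neutralized
  ph <- default_phantom(1)
  expect_lt(abs(ph$truth$volume_ratio - 0.868), 0.01)
})

test_that("zero-perturbation fixation yields a re-noised copy with identity truth", {
  ph <- simulate_exvivo(generate_invivo(phantom_config(seed = 4,
                                                       translation_mm = 0)),
                        shrinkage_percent = 0, deform_sd = 0,
                        tilt_x_deg = 0, tilt_y_deg = 0, rot_z_deg = 0)
  tr <- ph$truth$phys_sim
  expect_equal(tr$scale, 1, tolerance = 5e-3)
  expect_equal(rotation_angles_deg(tr), c(0, 0, 0), tolerance = 1e-9)
  # labels agree except at the removed thin section below the plane
  pts_z <- grid_world_points(ph$invivo)[, 3]
  above <- pts_z >= ph$truth$z0_ex + 0.5
  agree <- mean(ph$labels_exvivo[above] == ph$labels_invivo[above])
  expect_gt(agree, 0.98)
})

test_that("ground-truth transforms reproduce the per-frame landmarks", {
  ph <- default_phantom(1)
  # ex vivo landmarks map back to in vivo through the generation pull-back
  back <- apply_transform(ph$truth$G, ph$landmarks_exvivo$points)
  expect_lt(max(abs(back - ph$landmarks_invivo$points)), 1e-9)
  # stack landmarks are the ex vivo landmarks through the sectioning affine
  st <- apply_transform(ph$truth$stack_from_ex, ph$landmarks_exvivo$points)
  expect_lt(max(abs(st - ph$landmarks_stack$points)), 1e-12)
})

test_that("landmarks sit on the deformed tumor boundary", {
  ph <- default_phantom(1)
  surf <- histomri:::mask_surface(ph$labels_exvivo > 0)
  spts <- grid_world_points(ph$exvivo)[as.logical(surf), , drop = FALSE]
  for (i in seq_len(nrow(ph$landmarks_exvivo$points))) {
    d <- sqrt(min(rowSums(sweep(spts, 2,
                                ph$landmarks_exvivo$points[i, ])^2)))
    expect_lt(d, 1.5 * max(ph$exvivo$spacing))
  }
})

test_that("the reference plane is orthonormal and consistent across frames", {
  ph <- default_phantom(1)
  pl <- ph$plane
  g <- crossprod(cbind(pl$in_plane_axes, pl$normal))
  expect_equal(g, diag(3), tolerance = 1e-9)
  # the in vivo plane maps onto the ex vivo cut plane under the physical map
  p_ex <- apply_transform(ph$truth$phys_sim, pl$point)
  expect_equal(p_ex[1, 3], ph$truth$z0_ex, tolerance = 1e-9)
})

test_that("infeasible compartment fractions are rejected", {
  expect_error(phantom_config(fractions = c(viable = 0.8, necrotic = 0.3,
                                            hemorrhagic = 0.1)))
  expect_error(phantom_config(n_sections = 1))
})
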