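# Shared fixtures, memoized so expensive phantoms are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

acceptance_run <- function() {
  fixture("acc_runall", function() {
    run_all(file.path(tempdir(), "acc_runall"), seed = 1)
  })
}

default_phantom <- function(seed = 1) {
  fixture(paste0("phantom_", seed), function() {
    generate_phantom(phantom_config(seed = seed))
  })
}

# phantom under the controlled stacking-study conditions: jitter is the only
# perturbation (no fixation deformation, no frame misalignment, no noise)
jitter_only_phantom <- function(seed = 1) {
  fixture(paste0("jitter_phantom_", seed), function() {
    ph <- simulate_exvivo(generate_invivo(phantom_config(seed = seed)),
                          deform_sd = 0, tilt_x_deg = 0, tilt_y_deg = 0,
                          rot_z_deg = 0)
    simulate_sections(ph, rgb_noise_sd = 0, section_texture_sd = 0)
  })
}

# phantom with programmed shrinkage only (shrinkage-recovery conditions)
shrink_phantom <- function(seed) {
  fixture(paste0("shrink_phantom_", seed), function() {
    simulate_exvivo(generate_invivo(phantom_config(seed = seed)),
                    deform_sd = 0)
  })
}

# small random test volume
noise_volume <- function(seed = 1, d = c(16, 16, 16), spacing = 1) {
  set.seed(seed)
  volume_image(array(rnorm(prod(d)), d), spacing = rep(spacing, 3))
}

# independent brute-force mutual information (bits): plain loops over a
# partial-volume-binned joint histogram; written independently of the
# package's vectorized estimator
oracle_mi_pv <- function(f, m, nb = 32, frange = range(f),
                         mrange = range(m)) {
  uf <- pmin(pmax((f - frange[1]) / diff(frange) * (nb - 1), 0), nb - 1)
  um <- pmin(pmax((m - mrange[1]) / diff(mrange) * (nb - 1), 0), nb - 1)
  H <- matrix(0, nb, nb)
  for (i in seq_along(uf)) {
    f0 <- min(floor(uf[i]), nb - 2); wf <- uf[i] - f0
    m0 <- min(floor(um[i]), nb - 2); wm <- um[i] - m0
    H[f0 + 1, m0 + 1] <- H[f0 + 1, m0 + 1] + (1 - wf) * (1 - wm)
    H[f0 + 2, m0 + 1] <- H[f0 + 2, m0 + 1] + wf * (1 - wm)
    H[f0 + 1, m0 + 2] <- H[f0 + 1, m0 + 2] + (1 - wf) * wm
    H[f0 + 2, m0 + 2] <- H[f0 + 2, m0 + 2] + wf * wm
  }
  p <- H / sum(H)
  pf <- rowSums(p); pm <- colSums(p)
  s <- 0
  for (i in seq_len(nb)) for (j in seq_len(nb))
    if (p[i, j] > 0) s <- s + p[i, j] * log2(p[i, j] / (pf[i] * pm[j]))
  s
}

# registration configuration with the phantom's tumor mask for ex2in
ex2in_config <- function(phantom, realigned, seed) {
  cfg <- registration_config(seed = seed)
  lab <- resample(volume_image(phantom$labels_invivo * 1.0,
                               spacing = phantom$invivo$spacing),
                  NULL, realigned, scheme = "nearest")$values
  cfg$fixed_mask <- mask_dilate(round(lab) > 0, 3)
  cfg
}

smooth_volume_fixture <- function() {
  g <- as.matrix(expand.grid(0:19, 0:19, 0:19))
  volume_image(array(sin(g[, 1] / 4) + cos(g[, 2] / 5) + g[, 3] / 10,
                     c(20, 20, 20)), spacing = c(0.5, 0.5, 0.5))
}
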