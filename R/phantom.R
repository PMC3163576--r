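# Seeded synthetic tumor phantom: an in vivo MRI-like volume with viable /
# necrotic / hemorrhagic compartments, its fixed-and-shrunk ex vivo
# counterpart, a jittered RGB section stack, landmarks, VOI masks, and the
# exact ground-truth transforms connecting the three frames.

#' Phantom configuration
#'
#' Defaults emulate the study conditions: a subcutaneous tumor of roughly
#' 10 mm diameter (flat along z, its growth direction parallel to the skin),
#' 13.2 percent volume loss at fixation, sections cut from the reference
#' plane onwards at 80 um intervals with up to 40 (default 30) sections,
#' +1.9 percent in-plane expansion at sectioning, per-slice rigid jitter,
#' and T2*-like contrast in which necrosis is distinctly dark while viable
#' and hemorrhagic tissue overlap. MRI intensities are quantized to integers
#' as scanner magnitude images are.
#'
#' @param grid_shape in vivo / ex vivo grid size (cubic).
#' @param spacing isotropic voxel spacing, mm.
#' @param tumor_semiaxes ellipsoid semi-axes (mm) before lobular perturbation.
#' @param fractions target volume fractions of the tumor for the three
#'   compartments (remainder of the grid is background/agar).
#' @param lobe_amp relative amplitude of the lobular boundary perturbation.
#' @param shrinkage_percent programmed ex vivo volume loss (percent).
#' @param deform_sd,deform_detail_sd,deform_spacing the random fixation
#'   deformation: a long-wavelength component (coefficients correlated
#'   over twice the control spacing, std. dev. \code{deform_sd} mm per
#'   axis; the through-plane component is kept smaller so landmarks stay
#'   within the sectioned slab) plus a short-wavelength component
#'   (independent coefficients, std. dev. \code{deform_detail_sd} mm) on
#'   a control grid of \code{deform_spacing} mm. The short-wavelength
#'   part is what only the elastic registration stage can recover.
#' @param tilt_deg,inplane_rot_deg,translation_mm bounds of the random
#'   rigid misalignment of the ex vivo frame (out-of-plane tilt about each
#'   in-plane axis, in-plane rotation, translation per axis).
#' @param n_sections,section_interval,section_pixel_size,section_shape
#'   sectioning geometry (mm).
#' @param slide_offset_mm magnitude range of the random common in-plane
#'   offset of the specimen on the slides (the tissue never sits exactly
#'   centered; mounting is off by a couple of millimeters). The offset is
#'   shared by all sections, so it does not perturb slice-to-slice jitter;
#'   it dominates the pre-registration landmark error, matching the
#'   1.4 mm initial misalignment reported for plane-based alignment of
#'   real specimens.
#' @param expansion_percent in-plane volume expansion at sectioning.
#' @param cutting_compression_percent anisotropy of the sectioning
#'   deformation: microtome sections compress along the cutting direction
#'   and stretch across it (area-preserving on top of the global
#'   expansion), a well-known artifact of paraffin sectioning.
#' @param jitter_translation_px,jitter_rotation_deg per-slice rigid jitter
#'   bounds (uniform draws).
#' @param rgb_noise_sd per-channel Gaussian noise on the section RGB values
#'   (8-bit scale).
#' @param section_texture_sd std. dev. of the additive per-slice texture
#'   shared by the three channels of a pixel (staining/thickness variation;
#'   independent between slices, i.e. noise).
#' @param specimen_texture_sd std. dev. of the smooth 3D tissue texture
#'   attached to the specimen (cellular/stromal structure); adjacent
#'   sections share it, which is what anchors slice-to-slice registration
#'   in real material.
#' @param landmark_count landmarks placed at boundary features within the
#'   sectioned slab.
#' @param seed random seed; a fixed seed makes all generators bit-reproducible.
#' @export
phantom_config <- function(grid_shape = c(64, 64, 64),
                           spacing = 0.2,
                           tumor_semiaxes = c(4.8, 3.8, 2.6),
                           fractions = c(viable = 0.60, necrotic = 0.30,
                                         hemorrhagic = 0.10),
                           lobe_amp = 0.05,
                           shrinkage_percent = 13.2,
                           deform_sd = c(0.7, 0.7, 0.3),
                           deform_detail_sd = 0.25,
                           deform_spacing = 4,
                           tilt_deg = 2,
                           inplane_rot_deg = 2,
                           translation_mm = 0.2,
                           n_sections = 30,
                           section_interval = 0.08,
                           section_pixel_size = 0.1,
                           section_shape = c(176, 176),
                           slide_offset_mm = c(1.5, 3),
                           expansion_percent = 1.9,
                           cutting_compression_percent = 12,
                           jitter_translation_px = 5,
                           jitter_rotation_deg = 3,
                           rgb_noise_sd = 3,
                           section_texture_sd = 12,
                           specimen_texture_sd = 15,
                           landmark_count = 10,
                           seed = 1) {
  grid_shape <- rep(as.integer(grid_shape), length.out = 3)
  fr <- fractions
  stopifnot(all(fr >= 0), sum(fr) <= 1,
            all(c("viable", "necrotic", "hemorrhagic") %in% names(fr)),
            jitter_translation_px >= 0, jitter_rotation_deg >= 0,
            section_interval > 0, n_sections >= 2)
  structure(list(grid_shape = grid_shape, spacing = rep(spacing, 3),
                 tumor_semiaxes = tumor_semiaxes, fractions = fr,
                 lobe_amp = lobe_amp, shrinkage_percent = shrinkage_percent,
                 deform_sd = deform_sd, deform_detail_sd = deform_detail_sd,
                 deform_spacing = deform_spacing,
                 tilt_deg = tilt_deg, inplane_rot_deg = inplane_rot_deg,
                 translation_mm = translation_mm,
                 n_sections = as.integer(n_sections),
                 section_interval = section_interval,
                 section_pixel_size = section_pixel_size,
                 section_shape = rep(as.integer(section_shape), length.out = 2),
                 slide_offset_mm = slide_offset_mm,
                 expansion_percent = expansion_percent,
                 cutting_compression_percent = cutting_compression_percent,
                 jitter_translation_px = jitter_translation_px,
                 jitter_rotation_deg = jitter_rotation_deg,
                 rgb_noise_sd = rgb_noise_sd,
                 section_texture_sd = section_texture_sd,
                 specimen_texture_sd = specimen_texture_sd,
                 landmark_count = as.integer(landmark_count),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# per-compartment intensity models (integer-quantized on sampling)
phantom_intensities <- function() {
  list(invivo = list(mean = c(background = 60, viable = 110, necrotic = 28,
                              hemorrhagic = 104),
                     sd = c(background = 5, viable = 14, necrotic = 1.5,
                            hemorrhagic = 14)),
       exvivo = list(mean = c(background = 15, viable = 120, necrotic = 35,
                              hemorrhagic = 110),
                     sd = c(background = 3, viable = 14, necrotic = 1.5,
                            hemorrhagic = 14)),
       # H&E-like: viable dark purple, necrotic pale pink, hemorrhagic
       # red-dominant, slide background white; a shared additive texture
       # field makes the green/blue channels overlap between necrotic and
       # viable while the red channel stays well separated (eosin transmits
       # red), so red is the most discriminative channel by construction
       rgb = list(background = c(245, 245, 245),
                  viable = c(120, 85, 160),
                  necrotic = c(230, 120, 185),
                  hemorrhagic = c(210, 70, 95)))
}

# smooth random azimuthal lobe field (von Mises bumps around the in-plane
# azimuth): the lobules are ridges running along the sectioning axis, as
# tumor lobulation extends through consecutive sections; a fully 3D bump
# field would make the in-plane boundary features migrate between adjacent
# sections, which no slice-by-slice alignment could distinguish from jitter
lobe_field <- function(n_lobes = 6, kappa = 8) {
  phis <- runif(n_lobes, 0, 2 * pi)
  amps <- rnorm(n_lobes)
  function(u) { # u: n x 3 unit vectors (only the in-plane azimuth is used)
    az <- atan2(u[, 2], u[, 1])
    v <- exp(kappa * (cos(outer(az, phis, "-")) - 1)) %*% amps
    as.numeric(v)
  }
}

labels_to_ints <- function() c(background = 0L, viable = 1L, necrotic = 2L,
                               hemorrhagic = 3L)

sample_region_intensities <- function(labels, model) {
  lv <- labels_to_ints()
  out <- numeric(length(labels))
  for (nm in names(lv)) {
    sel <- labels == lv[[nm]]
    ns <- sum(sel)
    if (ns) out[sel] <- rnorm(ns, model$mean[[nm]], model$sd[[nm]])
  }
  pmax(round(out), 0)
}

# boundary voxels of a mask (6-connectivity)
mask_surface <- function(mask) {
  d <- dim(mask)
  inner <- mask
  for (a in 1:3) {
    hi <- array(FALSE, d); lo <- array(FALSE, d)
    n <- d[a]
    hi[slice_index(d, a, 1:(n - 1))] <- mask[slice_index(d, a, 2:n)]
    lo[slice_index(d, a, 2:n)] <- mask[slice_index(d, a, 1:(n - 1))]
    inner <- inner & hi & lo
  }
  mask & !inner
}

#' Generate the in vivo tumor phantom
#'
#' An ellipsoidal tumor with a lobular boundary, a nested necrotic core and
#' hemorrhagic pockets carved from the viable rim; T2*-like integer
#' intensities (necrotic distinctly darker; viable and hemorrhagic
#' overlapping); landmarks at boundary features within the slab that will be
#' sectioned; and the nominal reference cutting plane along the longest
#' tumor axis, perpendicular to the subcutaneous side.
#'
#' @param cfg a \code{\link{phantom_config}}.
#' @return an object of class \code{tumor_phantom} with elements
#'   \code{invivo}, \code{labels_invivo}, \code{landmarks_invivo},
#'   \code{plane}, \code{cfg}, \code{truth} (grown by the later simulation
#'   steps).
#' @export
generate_invivo <- function(cfg = phantom_config()) {
  set.seed(cfg$seed)
  ints <- phantom_intensities()
  d <- cfg$grid_shape
  sp <- cfg$spacing
  grid <- volume_image(array(0, d), spacing = sp, origin = c(0, 0, 0))
  ctr <- grid_center(grid)
  pts <- grid_world_points(grid)
  rel <- sweep(sweep(pts, 2, ctr), 2, cfg$tumor_semiaxes, "/")
  rho <- sqrt(rowSums(rel^2))
  u <- rel / pmax(rho, 1e-12)

  lob_t <- lobe_field()
  lob_n <- lobe_field()
  st <- lob_t(u); st <- st / max(abs(st))
  sn <- lob_n(u); sn <- sn / max(abs(sn))

  fr <- cfg$fractions
  fr_nec <- fr[["necrotic"]] / (fr[["viable"]] + fr[["necrotic"]] +
                                  fr[["hemorrhagic"]])
  tumor <- rho <= 1 + cfg$lobe_amp * st
  # necrotic core: a columnar (extruded along the cut normal) lobed region;
  # like the pockets below, an isotropically nested core would make the
  # in-plane content of adjacent sections differ by growth that sequential
  # stacking cannot distinguish from jitter. The in-plane radius is
  # calibrated by bisection so the realized necrotic fraction matches the
  # request.
  rho2 <- sqrt(rel[, 1]^2 + rel[, 2]^2)
  n_tumor <- sum(tumor)
  lo <- 0.1; hi <- 0.9
  for (it in 1:12) {
    s2 <- (lo + hi) / 2
    frac <- sum(tumor & rho2 <= s2 * (1 + cfg$lobe_amp * sn)) / n_tumor
    if (frac < fr_nec) lo <- s2 else hi <- s2
  }
  s_nec <- (lo + hi) / 2
  necro <- rho2 <= s_nec * (1 + cfg$lobe_amp * sn)
  labels <- integer(prod(d))
  labels[tumor] <- 1L
  labels[necro & tumor] <- 2L

  # hemorrhagic pockets carved from the viable rim until the target
  # fraction of the tumor volume is reached; pockets are columnar along the
  # sectioning axis (hemorrhage tracking vessels that run perpendicular to
  # the skin) -- isotropic pockets would appear and disappear between
  # adjacent sections, a through-plane feature turnover that sequential
  # stacking cannot distinguish from slice jitter
  target_h <- fr[["hemorrhagic"]] * n_tumor
  cand <- which(labels == 1L & rho2 > s_nec + 0.08 & rho2 < 0.8 & rho < 0.85)
  guard <- 0
  while (sum(labels == 3L) < target_h && length(cand) && guard < 60) {
    guard <- guard + 1
    cen <- pts[sample(cand, 1), ]
    r_b <- runif(1, 0.35, 0.6)
    hit <- labels == 1L &
      (pts[, 1] - cen[1])^2 + (pts[, 2] - cen[2])^2 <= r_b^2
    labels[hit] <- 3L
  }

  vol <- array(sample_region_intensities(labels, ints$invivo), d)
  labels <- array(labels, d)

  # nominal reference plane: normal +z, spanning the longest (x) axis,
  # offset below center so the removed cap is small while the first
  # sections already have substantial cross-sections; the sectioned slab
  # extends from the plane towards +z
  z0 <- ctr[3] - 0.6 * cfg$tumor_semiaxes[3]
  z0 <- round(z0 / sp[3]) * sp[3] # snap to a grid node
  plane <- reference_plane(c(0, 0, 1), c(ctr[1], ctr[2], z0),
                           cbind(c(1, 0, 0), c(0, 1, 0)))

  # landmarks: farthest-point sample of tumor boundary voxels inside the slab
  slab <- cfg$n_sections * cfg$section_interval
  surf <- mask_surface(array(labels > 0, d))
  cand_lm <- which(surf & pts[, 3] >= z0 + 0.4 & pts[, 3] <= z0 + 0.8 * slab)
  if (length(cand_lm) < cfg$landmark_count)
    stop("infeasible geometry: too few boundary voxels inside the slab")
  cp <- pts[cand_lm, , drop = FALSE]
  sel <- integer(cfg$landmark_count)
  sel[1] <- which.max(abs(st[cand_lm])) # most lobular boundary feature
  dmin <- rowSums(sweep(cp, 2, cp[sel[1], ])^2)
  for (i in seq_len(cfg$landmark_count - 1)) {
    sel[i + 1] <- which.max(dmin)
    dmin <- pmin(dmin, rowSums(sweep(cp, 2, cp[sel[i + 1], ])^2))
  }
  lm <- cp[sel, , drop = FALSE]
  rownames(lm) <- sprintf("L%02d", seq_len(nrow(lm)))

  structure(list(
    invivo = volume_image(vol, spacing = sp, origin = c(0, 0, 0)),
    labels_invivo = labels,
    landmarks_invivo = landmark_set(lm, observer = "truth", image = "invivo"),
    plane = plane,
    center = ctr,
    cfg = cfg,
    truth = list()
  ), class = "tumor_phantom")
}

#' Region masks of a phantom frame
#'
#' @param phantom a \code{tumor_phantom}.
#' @param frame which frame's labels to use.
#' @return named list of logical arrays (\code{tumor}, \code{viable},
#'   \code{necrotic}, \code{hemorrhagic}).
#' @export
phantom_masks <- function(phantom, frame = c("invivo", "exvivo")) {
  frame <- match.arg(frame)
  lab <- phantom[[paste0("labels_", frame)]]
  if (is.null(lab)) stop("frame not generated yet: ", frame)
  list(tumor = lab > 0, viable = lab == 1L, necrotic = lab == 2L,
       hemorrhagic = lab == 3L)
}

#' Simulate the ex vivo (fixed, shrunken, deformed) phantom
#'
#' Applies the physical fixation map: isotropic shrinkage with determinant
#' \code{1 - shrinkage_percent/100}, a small random rigid misalignment, and
#' a smooth random B-spline deformation; re-noises the intensities with the
#' ex vivo contrast model; crops everything below the reference cutting
#' plane (the physically removed thin section), and records the exact
#' generation transform and the induced in vivo reference plane.
#'
#' @param phantom result of \code{\link{generate_invivo}}.
#' @param shrinkage_percent,tilt_x_deg,tilt_y_deg,rot_z_deg optional
#'   overrides of the configured shrinkage and the randomly drawn rotation
#'   (degrees), for controlled experiments.
#' @param deform_sd,deform_detail_sd optional overrides of the deformation
#'   amplitudes (a zero \code{deform_sd} also disables the detail part).
#' @return the phantom with \code{exvivo}, \code{labels_exvivo},
#'   \code{landmarks_exvivo}, \code{plane} (exact in vivo plane),
#'   \code{plane_exvivo}, and \code{truth} entries added; \code{truth$G} is
#'   the generation pull-back (ex vivo world to in vivo world) and
#'   \code{truth$phys_sim} the physical fixation similarity (in vivo to
#'   ex vivo).
#' @export
simulate_exvivo <- function(phantom, shrinkage_percent = NULL,
                            tilt_x_deg = NULL, tilt_y_deg = NULL,
                            rot_z_deg = NULL, deform_sd = NULL,
                            deform_detail_sd = NULL) {
  cfg <- phantom$cfg
  set.seed(cfg$seed + 1000L)
  if (is.null(shrinkage_percent)) shrinkage_percent <- cfg$shrinkage_percent
  if (is.null(deform_sd)) deform_sd <- cfg$deform_sd
  if (is.null(deform_detail_sd)) {
    deform_detail_sd <- if (all(deform_sd == 0)) 0 else cfg$deform_detail_sd
  }
  tilt_x <- if (is.null(tilt_x_deg)) runif(1, -cfg$tilt_deg, cfg$tilt_deg)
            else tilt_x_deg
  tilt_y <- if (is.null(tilt_y_deg)) runif(1, -cfg$tilt_deg, cfg$tilt_deg)
            else tilt_y_deg
  rot_z <- if (is.null(rot_z_deg))
             runif(1, -cfg$inplane_rot_deg, cfg$inplane_rot_deg)
           else rot_z_deg
  tr <- runif(3, -cfg$translation_mm, cfg$translation_mm)

  s_phys <- (1 - shrinkage_percent / 100)^(1 / 3)
  ang <- c(tilt_x, tilt_y, rot_z) * pi / 180
  ctr <- phantom$center
  R <- euler_to_matrix(ang)

  # smooth random deformation, expressed in the ex vivo frame
  sp <- cfg$spacing
  d <- cfg$grid_shape
  ext <- (d - 1) * sp
  nc <- as.integer(ceiling(ext / cfg$deform_spacing) + 3)
  deform_sd <- rep(deform_sd, length.out = 3)
  coef <- array(0, c(nc, 3L))
  kc <- gauss_kernel(2) # coefficients correlated over ~2 control spacings
  for (a in 1:3) {
    smooth_part <- 0
    if (deform_sd[a] > 0) {
      raw <- rnorm(prod(nc))
      for (ax in 0:2) raw <- cpp_smooth_axis(raw, nc, kc, ax)
      smooth_part <- raw / sd(raw) * deform_sd[a]
    }
    detail_scale <- deform_detail_sd * (if (a == 3) 0.5 else 1)
    coef[, , , a] <- smooth_part + rnorm(prod(nc), 0, detail_scale)
  }
  # Remove the field's coherent rotation and mean translation. A random
  # coefficient field carries an average swirl of several degrees across
  # the tumor, which no real fixation produces and which the linear
  # registration stages would otherwise absorb into their pose; the
  # symmetric (strain) part and the nonlinear residual stay. Cubic
  # B-splines reproduce linear fields exactly when the coefficients equal
  # the field at the control points, so the correction is exact.
  if (any(deform_sd > 0) || deform_detail_sd > 0) {
    # probe the field over the tumor region (where the registration metric
    # lives), not the whole box
    ctr_ex0 <- ctr + tr
    semi_ex <- 0.9 * s_phys * cfg$tumor_semiaxes
    gu <- seq(-1, 1, length.out = 9)
    pg <- as.matrix(expand.grid(gu, gu, gu))
    pg <- pg[rowSums(pg^2) <= 1, , drop = FALSE]
    probe <- sweep(sweep(pg, 2, semi_ex, "*"), 2, ctr_ex0, "+")
    bs0 <- bspline3(grid_origin = -cfg$deform_spacing * c(1, 1, 1),
                    grid_spacing = rep(cfg$deform_spacing, 3), coef = coef)
    Dp <- bspline_displacement(bs0, probe)
    pc <- sweep(probe, 2, colMeans(probe))
    A <- t(qr.solve(cbind(1, pc), Dp)) # rows: D components; cols: 1, x, y, z
    b <- A[, 1]
    W <- (A[, 2:4] - t(A[, 2:4])) / 2 # antisymmetric (rotation) part
    cp_idx <- as.matrix(expand.grid(seq_len(nc[1]) - 1, seq_len(nc[2]) - 1,
                                    seq_len(nc[3]) - 1))
    cp_pos <- sweep(cp_idx * cfg$deform_spacing, 2,
                    cfg$deform_spacing * c(1, 1, 1), "-")
    corr <- sweep(sweep(cp_pos, 2, colMeans(probe)) %*% t(W), 2, b, "+")
    for (a in 1:3) coef[, , , a] <- coef[, , , a] - array(corr[, a], nc)
  }
  bs <- bspline3(grid_origin = -cfg$deform_spacing * c(1, 1, 1),
                 grid_spacing = rep(cfg$deform_spacing, 3), coef = coef)

  make_G <- function(scale_pb) { # ex vivo world -> in vivo world
    sim_inv <- similarity3(matrix_to_euler(t(R)),
                           as.numeric(-scale_pb * (t(R) %*% tr)),
                           ctr, scale_pb)
    composite_transform(bs, sim_inv)
  }
  grid <- volume_image(array(0, d), spacing = sp, origin = c(0, 0, 0))
  pts <- grid_world_points(grid)
  lab_in <- phantom$labels_invivo
  labels_via <- function(G) {
    src <- apply_transform(G, pts)
    as.integer(round(cpp_interp3(as.numeric(lab_in), dim(lab_in),
                                 world_to_index(phantom$invivo, src), 0L, 0)))
  }
  # the random deformation is not volume-neutral for a single draw; a
  # compensating isotropic rescale enforces the programmed global volume
  # change exactly (fixation shrinkage carries the volume change, the
  # residual deformation is quasi-incompressible bending)
  scale_pb <- 1 / s_phys
  G <- make_G(scale_pb)
  lab_ex <- labels_via(G)
  target <- 1 - shrinkage_percent / 100
  for (it in 1:4) {
    r0 <- sum(lab_ex > 0) / sum(lab_in > 0)
    if (abs(r0 - target) < 0.003) break
    scale_pb <- scale_pb * (r0 / target)^(1 / 3)
    G <- make_G(scale_pb)
    lab_ex <- labels_via(G)
  }
  phys_sim <- similarity3(ang, tr, ctr, 1 / scale_pb) # in vivo -> ex vivo
  tumor_ctr_ex <- as.numeric(apply_transform(phys_sim, ctr))
  z0_ex <- tumor_ctr_ex[3] - 0.6 * (1 / scale_pb) * cfg$tumor_semiaxes[3]
  z0_ex <- round(z0_ex / sp[3]) * sp[3]
  lab_ex <- as.integer(round(lab_ex))
  volume_ratio <- sum(lab_ex > 0) / sum(phantom$labels_invivo > 0)
  lab_ex[pts[, 3] < z0_ex] <- 0L # the physically removed thin section
  lab_ex <- array(lab_ex, d)

  ints <- phantom_intensities()
  vol_ex <- array(sample_region_intensities(as.integer(lab_ex), ints$exvivo), d)

  # landmarks: solve G(L_ex) = L_in, i.e. L_ex + D(L_ex) = phys_sim(L_in)
  w <- apply_transform(phys_sim, phantom$landmarks_invivo$points)
  y <- w
  for (i in 1:25) {
    y_new <- w - bspline_displacement(bs, y)
    if (max(abs(y_new - y)) < 1e-12) { y <- y_new; break }
    y <- y_new
  }
  rownames(y) <- rownames(phantom$landmarks_invivo$points)

  # exact in vivo reference plane induced by the ex vivo cut at z = z0_ex
  n_in <- as.numeric(t(R) %*% c(0, 0, 1))
  sim_inv <- G$components[[2]]
  p_in <- as.numeric(apply_transform(sim_inv,
                                     c(tumor_ctr_ex[1], tumor_ctr_ex[2], z0_ex)))
  ax <- cbind(as.numeric(t(R) %*% c(1, 0, 0)), as.numeric(t(R) %*% c(0, 1, 0)))
  phantom$plane <- reference_plane(n_in, p_in, ax)
  phantom$plane_exvivo <- reference_plane(c(0, 0, 1),
                                          c(tumor_ctr_ex[1], tumor_ctr_ex[2],
                                            z0_ex),
                                          cbind(c(1, 0, 0), c(0, 1, 0)))
  phantom$exvivo <- volume_image(vol_ex, spacing = sp, origin = c(0, 0, 0))
  phantom$labels_exvivo <- lab_ex
  phantom$landmarks_exvivo <- landmark_set(y, observer = "truth",
                                           image = "exvivo")
  phantom$truth$G <- G
  phantom$truth$phys_sim <- phys_sim
  phantom$truth$deformation <- bs
  phantom$truth$shrinkage_percent <- shrinkage_percent
  phantom$truth$volume_ratio <- volume_ratio # uncropped ex/in mask ratio
  phantom$truth$tilt_deg <- c(x = tilt_x, y = tilt_y, z = rot_z)
  phantom$truth$z0_ex <- z0_ex
  phantom$truth$tumor_center_ex <- tumor_ctr_ex
  phantom
}

#' Simulate sectioning of the ex vivo phantom into an RGB H&E-like stack
#'
#' Cuts sections parallel to the reference plane from the plane onwards at
#' the configured interval, applies a small global in-plane expansion and a
#' recorded random rigid jitter per slice, and renders the region labels
#' with H&E-like colors (viable dark purple, necrotic pale pink,
#' hemorrhagic red-dominant) constructed so that the red channel maximizes
#' necrotic/viable separability.
#'
#' @param phantom result of \code{\link{simulate_exvivo}}.
#' @param rgb_noise_sd,section_texture_sd,jitter_translation_px,jitter_rotation_deg
#'   optional overrides of the configured noise and jitter bounds (set the
#'   two noise levels to 0 for a noiseless stack).
#' @return the phantom with \code{sections} (a \code{\link{section_stack}}),
#'   \code{section_labels}, \code{landmarks_stack}, and truth entries
#'   \code{jitter} (per-slice \code{\link{rigid2}}) and
#'   \code{stack_from_ex} (the exact ex vivo to stack affine) added.
#' @export
simulate_sections <- function(phantom, rgb_noise_sd = NULL,
                              section_texture_sd = NULL,
                              jitter_translation_px = NULL,
                              jitter_rotation_deg = NULL) {
  cfg <- phantom$cfg
  if (is.null(phantom$exvivo)) stop("run simulate_exvivo first")
  set.seed(cfg$seed + 2000L)
  if (is.null(rgb_noise_sd)) rgb_noise_sd <- cfg$rgb_noise_sd
  if (is.null(section_texture_sd)) section_texture_sd <- cfg$section_texture_sd
  if (is.null(jitter_translation_px))
    jitter_translation_px <- cfg$jitter_translation_px
  if (is.null(jitter_rotation_deg))
    jitter_rotation_deg <- cfg$jitter_rotation_deg

  px <- cfg$section_pixel_size
  shp <- cfg$section_shape
  n <- cfg$n_sections
  z0 <- phantom$truth$z0_ex
  ctr2 <- phantom$truth$tumor_center_ex[1:2]
  ext_z <- (dim(phantom$exvivo$values)[3] - 1) * phantom$exvivo$spacing[3] +
    phantom$exvivo$origin[3]
  if (z0 + (n - 1) * cfg$section_interval > ext_z)
    stop("section interval too large: slab extends past the specimen")
  e <- sqrt(1 + cfg$expansion_percent / 100) # in-plane linear expansion
  comp <- 1 - cfg$cutting_compression_percent / 100
  e_xy <- c(e / sqrt(comp), e * sqrt(comp)) # area preserved: e_x * e_y = e^2
  off_r <- runif(1, min(cfg$slide_offset_mm), max(cfg$slide_offset_mm))
  off_a <- runif(1, 0, 2 * pi)
  placement <- off_r * c(cos(off_a), sin(off_a))
  o2d <- ctr2 - (shp - 1) / 2 * px
  qc <- (shp - 1) / 2 * px # section-frame center, mm
  jt <- jitter_translation_px * px
  jr <- jitter_rotation_deg * pi / 180

  ints <- phantom_intensities()
  rgb_tab <- rbind(ints$rgb$background, ints$rgb$viable, ints$rgb$necrotic,
                   ints$rgb$hemorrhagic)
  q <- grid_points_2d(shp, px)
  lab_ex <- phantom$labels_exvivo
  # smooth per-channel color volumes on the ex vivo grid; sections are
  # trilinear samples of these, so adjacent sections are consistent
  # sub-pixel samplings of one continuous stained specimen; a smooth 3D
  # texture field attached to the tissue provides the dense structure that
  # adjacent real sections share
  tex3d <- 0
  if (cfg$specimen_texture_sd > 0) {
    d_ex <- dim(lab_ex)
    raw <- matrix(rnorm(d_ex[1] * d_ex[2]), d_ex[1], d_ex[2])
    k_in <- gauss_kernel(1.0)
    sm2 <- cpp_smooth_axis(as.numeric(raw), c(d_ex[1:2], 1L), k_in, 0L)
    sm2 <- cpp_smooth_axis(sm2, c(d_ex[1:2], 1L), k_in, 1L)
    # the texture is extruded along the sectioning axis (stromal strands
    # perpendicular to the skin): adjacent sections must share their
    # texture, since in-plane texture flow between neighbouring sections
    # is indistinguishable from slice jitter
    sm3 <- array(rep(sm2, d_ex[3]), d_ex)
    tex3d <- sm3 / sd(sm2) * cfg$specimen_texture_sd * (lab_ex > 0)
  }
  color_ex <- lapply(1:3, function(ch)
    array(rgb_tab[as.integer(lab_ex) + 1L, ch], dim(lab_ex)) + tex3d)
  sections <- vector("list", n)
  sec_labels <- vector("list", n)
  jitters <- vector("list", n)
  for (k in seq_len(n)) {
    theta <- if (k == 1) 0 else runif(1, -jr, jr)
    tau <- if (k == 1) c(0, 0) else runif(2, -jt, jt)
    # recorded about the section center: the physical jitter acts about the
    # (offset) tissue position, so re-center its translation
    Rj <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    jitters[[k]] <- rigid2(theta,
                           tau + as.numeric((diag(2) - Rj) %*% placement), qc)
    Rm <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
    # pull-back: slide pixel -> ex vivo in-plane point (the tissue center
    # sits at qc + placement on every slide)
    r <- sweep(sweep(sweep(q, 2, qc + placement + tau) %*% t(Rm), 2, e_xy,
                     "/"), 2, ctr2, "+")
    wpts <- cbind(r, z0 + (k - 1) * cfg$section_interval)
    widx <- world_to_index(phantom$exvivo, wpts)
    lab <- as.integer(round(cpp_interp3(as.numeric(lab_ex), dim(lab_ex),
                                        widx, 0L, 0)))
    img <- array(0, c(shp, 3L))
    tex <- if (section_texture_sd > 0)
      rnorm(length(lab), 0, section_texture_sd) else 0
    for (ch in 1:3) {
      v <- cpp_interp3(as.numeric(color_ex[[ch]]), dim(lab_ex), widx, 1L,
                       rgb_tab[1, ch]) + tex
      if (rgb_noise_sd > 0) v <- v + rnorm(length(v), 0, rgb_noise_sd)
      img[, , ch] <- matrix(pmin(pmax(round(v), 0), 255), shp[1], shp[2])
    }
    sections[[k]] <- img
    sec_labels[[k]] <- matrix(lab, shp[1], shp[2])
  }

  # exact ex vivo world -> stack world affine (jitter-free reconstruction)
  cc <- c(ctr2, z0)
  tt <- c(qc + placement - ctr2, -z0)
  stack_from_ex <- affine3(diag(c(e_xy, 1)), tt, cc)
  lm_st <- apply_transform(stack_from_ex, phantom$landmarks_exvivo$points)
  rownames(lm_st) <- rownames(phantom$landmarks_exvivo$points)

  phantom$sections <- section_stack(sections, pixel_size = px,
                                    interval = cfg$section_interval,
                                    thickness = 0.004, units = "mm")
  phantom$section_labels <- sec_labels
  phantom$landmarks_stack <- landmark_set(lm_st, observer = "truth",
                                          image = "stack")
  phantom$truth$jitter <- jitters
  phantom$truth$slide_placement <- placement
  phantom$truth$stack_from_ex <- stack_from_ex
  phantom
}

#' Generate the complete phantom (in vivo, ex vivo, sections)
#'
#' Convenience wrapper chaining \code{\link{generate_invivo}},
#' \code{\link{simulate_exvivo}} and \code{\link{simulate_sections}}.
#' @param cfg a \code{\link{phantom_config}}.
#' @param ... overrides passed to \code{\link{simulate_exvivo}}.
#' @export
generate_phantom <- function(cfg = phantom_config(), ...) {
  simulate_sections(simulate_exvivo(generate_invivo(cfg), ...))
}
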