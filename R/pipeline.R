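# The three named registration procedures of the bottom-up path --
# stacking (stacking.R), stack2ex, ex2in -- plus the automatic stack2in
# concatenation and color warping.

stage_result <- function(init, rigid, affine, elastic_composite, metrics,
                         fixed, moving) {
  elastic <- NULL
  composite <- if (!is.null(elastic_composite)) elastic_composite
               else if (!is.null(affine)) affine
               else rigid
  if (!is.null(elastic_composite) && inherits(elastic_composite, "composite3"))
    elastic <- elastic_composite$components[[1]]
  structure(list(init = init, rigid = rigid, affine = affine,
                 elastic = elastic, composite = composite,
                 metrics = metrics,
                 fixed_geom = geom_signature(fixed),
                 moving_geom = geom_signature(moving)),
            class = "stage_result")
}

geom_signature <- function(vol) {
  list(dim = dim(vol$values), spacing = vol$spacing, origin = vol$origin,
       direction = vol$direction)
}

#' Transform of a stage at a given refinement level
#'
#' @param stage a \code{stage_result}.
#' @param level one of \code{"init"}, \code{"rigid"}, \code{"affine"},
#'   \code{"elastic"} (the full composite).
#' @export
stage_transform <- function(stage, level = c("elastic", "affine", "rigid",
                                             "init")) {
  level <- match.arg(level)
  t <- switch(level, init = stage$init, rigid = stage$rigid,
              affine = stage$affine, elastic = stage$composite)
  if (is.null(t)) stop("stage has no ", level, " transform")
  t
}

#' @export
print.stage_result <- function(x, ...) {
  cat("<stage_result> stages:",
      paste(names(x$metrics), collapse = " -> "), "\n")
  cat("  metric:", paste(sprintf("%.4f", x$metrics), collapse = " -> "), "\n")
  invisible(x)
}

#' Dilate a binary mask (6-connectivity)
#'
#' Registration masks are conventionally dilated by a few voxels so the
#' metric sees the tumor boundary transition from both sides; without the
#' shell, a mask restricted exactly to the tumor lets a contracting
#' transform avoid the boundary zone and biases the recovered scale.
#'
#' @param mask logical 3D array.
#' @param iterations dilation steps (voxels).
#' @export
mask_dilate <- function(mask, iterations = 2) {
  d <- dim(mask)
  m <- as.logical(mask); dim(m) <- d
  for (i in seq_len(iterations)) {
    grown <- m
    for (a in 1:3) {
      n <- d[a]
      if (n < 2) next
      hi <- array(FALSE, d); lo <- array(FALSE, d)
      hi[slice_index(d, a, 1:(n - 1))] <- m[slice_index(d, a, 2:n)]
      lo[slice_index(d, a, 2:n)] <- m[slice_index(d, a, 1:(n - 1))]
      grown <- grown | hi | lo
    }
    m <- grown
  }
  m
}

# Otsu's threshold on a 64-bin histogram: default foreground detector when
# no tumor mask is supplied
otsu_threshold <- function(v, bins = 64) {
  r <- range(v)
  if (r[1] == r[2]) return(r[1])
  br <- seq(r[1], r[2], length.out = bins + 1)
  h <- tabulate(pmin(findInterval(v, br, all.inside = TRUE), bins), bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-(bins + 1)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[bins]
  sb <- (mu_t * w0 - mu)^2 / pmax(w0 * (1 - w0), 1e-12)
  mids[which.max(sb[-bins])]
}

foreground_mask <- function(vol) {
  v <- vol$values
  v > otsu_threshold(as.numeric(v))
}

# histology foreground: tissue is darker than the white slide background in
# at least one channel
stack_foreground <- function(stackres) {
  r <- stackres$channels$red$values
  g <- stackres$channels$green$values
  b <- stackres$channels$blue$values
  pmin(r, pmin(g, b)) < 0.9 * max(r, g, b)
}

center_of_mass <- function(vol, mask) {
  pts <- grid_world_points(vol)
  colMeans(pts[as.logical(mask), , drop = FALSE])
}

# center-of-mass initialization: the reference plane fixes the out-of-plane
# pose (both frames start at the plane); the remaining offset -- in-plane
# position and the frames' different world coordinates of the plane -- is
# aligned by foreground centers of mass
inplane_com_init <- function(fixed, fixed_mask, moving, moving_mask) {
  cf <- center_of_mass(fixed, fixed_mask)
  cm <- center_of_mass(moving, moving_mask)
  # rotation center at the tumor center of mass decorrelates the rotation
  # and translation parameters during optimization
  rigid3(translation = cm - cf, center = cf)
}

full_metric <- function(fixed, moving, t, cfg) {
  metric_on_pair(fixed, moving, t, cfg, samples = "all")$value
}

run_stages <- function(fixed, moving, models, cfg, init, restarts = 2) {
  metrics <- c(init = full_metric(fixed, moving, init, cfg))
  rigid_t <- NULL; affine_t <- NULL; elastic_t <- NULL
  t_cur <- init
  v_prev <- metrics[["init"]]
  for (i in seq_along(models)) {
    m <- models[i]
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i
    t_new <- register(fixed, moving, model = m, cfg = cfg_i, init = t_cur)
    # a stochastic search can fail to leave the initialization's basin;
    # restart it from shifted random substreams until the stage improves
    # the full-sample metric (or the restart budget is exhausted)
    tries <- 0
    while (attr(t_new, "metric_value") >= v_prev - 1e-8 && tries < restarts) {
      tries <- tries + 1
      cfg_i$seed <- cfg$seed + i + 1000L * tries
      t_retry <- register(fixed, moving, model = m, cfg = cfg_i, init = t_cur)
      if (attr(t_retry, "metric_value") < attr(t_new, "metric_value"))
        t_new <- t_retry
    }
    t_cur <- t_new
    metrics[m] <- attr(t_cur, "metric_value")
    v_prev <- metrics[[m]]
    if (m == "rigid") rigid_t <- t_cur
    else if (m %in% c("affine", "similarity")) affine_t <- t_cur
    else elastic_t <- t_cur
  }
  names(metrics)[names(metrics) == "bspline"] <- "elastic"
  stage_result(init, rigid_t, affine_t, elastic_t, metrics, fixed, moving)
}

#' Register the 3D histology stack to the ex vivo MRI (stack2ex)
#'
#' Three-step registration of gradually increasing degrees of freedom
#' (rigid, full affine, B-spline) of the histology stack (moving, driver
#' channel) to the ex vivo MRI (fixed), both anchored at the reference
#' cutting plane (slice 0 / realigned), which initializes the out-of-plane
#' pose; the in-plane offset is initialized by aligning foreground centers
#' of mass. Mutual information throughout (MRI vs histology contrast).
#'
#' @param stackres a \code{\link{stack_sections}} result.
#' @param exvivo ex vivo MRI \code{\link{volume_image}}, realigned so the
#'   reference plane is slice 0 (see
#'   \code{\link{realign_to_reference_plane}}).
#' @param cfg a \code{\link{registration_config}}; \code{cfg$fixed_mask}
#'   should restrict the metric to tumor tissue within the sectioned slab
#'   (an intensity-threshold foreground mask restricted to the stack's z
#'   extent is used when absent).
#' @param stages subset of the three stages to run.
#' @return a \code{stage_result}; the composite maps ex vivo world points
#'   into the stack frame (pull-back).
#' @export
stack2ex <- function(stackres, exvivo, cfg = registration_config(),
                     stages = c("rigid", "affine", "bspline")) {
  moving <- stackres$channels[[stackres$driver_channel]]
  if (is.null(cfg$fixed_mask)) {
    zmax <- (dim(moving$values)[3] - 1) * moving$spacing[3]
    zw <- grid_world_points(exvivo)[, 3]
    slab <- array(zw >= exvivo$origin[3] & zw <= exvivo$origin[3] + zmax,
                  dim(exvivo$values))
    cfg$fixed_mask <- foreground_mask(exvivo) & slab
  }
  init <- inplane_com_init(exvivo, cfg$fixed_mask, moving,
                           stack_foreground(stackres))
  res <- tryCatch(
    run_stages(exvivo, moving, stages, cfg, init),
    error = function(e) {
      if (grepl("insufficient overlap", conditionMessage(e)))
        stop("stack2ex: ", conditionMessage(e),
             " -- do the stack and the ex vivo volume start at the same ",
             "reference plane?", call. = FALSE)
      stop(e)
    })
  res
}

#' Register the ex vivo MRI to the realigned in vivo MRI (ex2in)
#'
#' Realigns the in vivo volume by the reference plane, then runs the
#' three-step registration (rigid, affine with isotropic scaling, B-spline)
#' of the ex vivo MRI (moving) to the realigned in vivo MRI (fixed). The
#' similarity stage's scale accounts for the global fixation volume change:
#' its determinant in the pull-back direction is the physical shrinkage
#' factor (see \code{\link{global_volume_change}}).
#'
#' @param exvivo ex vivo MRI (plane at slice 0).
#' @param invivo in vivo MRI in its native frame.
#' @param plane the reference plane in the in vivo frame; \code{NULL} if
#'   \code{invivo} is already realigned.
#' @param cfg a \code{\link{registration_config}} (a tumor mask on the
#'   realigned grid in \code{cfg$fixed_mask} is recommended).
#' @param stages stages to run; \code{"similarity"} is the affine step
#'   restricted to isotropic scaling (default); use \code{"affine"} for a
#'   full 12-DOF middle stage.
#' @return a \code{stage_result} (composite: realigned in vivo world to
#'   ex vivo world) with the realigned fixed volume attached as
#'   \code{$fixed_realigned}.
#' @export
ex2in <- function(exvivo, invivo, plane = NULL, cfg = registration_config(),
                  stages = c("rigid", "similarity", "bspline")) {
  fixed <- if (!is.null(plane))
    realign_to_reference_plane(invivo, plane, out_spacing = exvivo$spacing)
  else invivo
  if (is.null(cfg$fixed_mask)) cfg$fixed_mask <- foreground_mask(fixed)
  init <- inplane_com_init(fixed, cfg$fixed_mask, exvivo,
                           foreground_mask(exvivo))
  res <- tryCatch(
    run_stages(fixed, exvivo, stages, cfg, init),
    error = function(e) {
      if (grepl("insufficient overlap", conditionMessage(e)))
        stop("ex2in: ", conditionMessage(e),
             " -- reference plane mismatch between the realigned in vivo ",
             "and ex vivo volumes?", call. = FALSE)
      stop(e)
    })
  res$fixed_realigned <- fixed
  res
}

#' Concatenate stack2ex and ex2in and warp the color stack (stack2in)
#'
#' Builds the final composite transform mapping (realigned) in vivo world
#' points to the histology stack frame and warps each color channel of the
#' stack independently onto the in vivo grid (linear interpolation; masks
#' should be warped with nearest-neighbor via \code{\link{resample}}).
#'
#' @param s2e \code{\link{stack2ex}} result.
#' @param e2i \code{\link{ex2in}} result.
#' @param color_stack the \code{\link{stack_sections}} result to warp.
#' @param invivo_grid \code{\link{volume_image}} supplying the output grid
#'   (default: the realigned in vivo volume of \code{e2i}).
#' @return list with \code{volume} (named list of three warped channel
#'   \code{volume_image}s) and \code{transform} (the composite).
#' @export
stack2in <- function(s2e, e2i, color_stack, invivo_grid = NULL) {
  if (is.null(invivo_grid)) invivo_grid <- e2i$fixed_realigned
  if (is.null(invivo_grid)) stop("no in vivo grid available")
  sg <- s2e$fixed_geom; eg <- e2i$moving_geom
  if (!isTRUE(all.equal(sg, eg, tolerance = 1e-8)))
    stop("frame mismatch: stack2ex was fitted against a different ex vivo ",
         "grid than ex2in's moving image")
  composite <- composite_transform(e2i$composite, s2e$composite)
  volume <- lapply(color_stack$channels, resample, transform = composite,
                   reference = invivo_grid, scheme = "linear", fill = 255)
  list(volume = volume, transform = composite)
}

#' Reference-plane identification between two plane-anchored frames
#'
#' The transform that maps points of one plane-anchored frame to the other
#' purely by their geometry: the plane points (at the in-plane center of
#' slice 0) coincide and the grid axes align. This is the correspondence
#' available before any registration, i.e. the "initial" alignment the
#' reference cutting plane provides by itself.
#'
#' @param from,to plane-anchored \code{\link{volume_image}}s (slice 0 on
#'   the plane, plane point at the in-plane center of slice 0).
#' @return an \code{\link{affine3}} mapping \code{from}-world points to
#'   \code{to}-world points.
#' @export
plane_identification <- function(from, to) {
  ctr_idx <- function(v) c((dim(v$values)[1:2] - 1) / 2, 0)
  p_f <- as.numeric(index_to_world(from, ctr_idx(from)))
  p_t <- as.numeric(index_to_world(to, ctr_idx(to)))
  M <- to$direction %*% t(from$direction)
  affine3(matrix = M, translation = p_t - p_f, center = p_f)
}

#' Landmark RMS per registration level through the full chain
#'
#' Maps in vivo landmarks through the concatenated stack2in transform built
#' from each refinement level and reports the RMS distance to the
#' corresponding stack-frame landmarks -- the per-step accuracy table of
#' the evaluation. The \code{initial} level is the alignment the reference
#' plane provides by itself (\code{\link{plane_identification}}, when
#' supplied); \code{rigid}, \code{affine} and \code{elastic} use the
#' recovered stage transforms of both steps.
#'
#' @param s2e,e2i stage results.
#' @param lm_invivo landmarks in the (realigned) in vivo world frame.
#' @param lm_stack corresponding landmarks in the stack frame.
#' @param t_initial optional transform giving the pre-registration
#'   correspondence (default: the concatenated stage initializations).
#' @return named numeric vector of RMS distances (mm).
#' @export
stagewise_landmark_rms <- function(s2e, e2i, lm_invivo, lm_stack,
                                   t_initial = NULL) {
  levels <- c("rigid", "affine", "elastic")
  out <- vapply(levels, function(lv) {
    t2 <- compose_transforms(stage_transform(e2i, lv),
                             stage_transform(s2e, lv))
    landmark_rms(lm_invivo, lm_stack, t = t2)
  }, 0)
  t0 <- if (!is.null(t_initial)) t_initial
        else compose_transforms(stage_transform(e2i, "init"),
                                stage_transform(s2e, "init"))
  c(initial = landmark_rms(lm_invivo, lm_stack, t = t0), out)
}
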