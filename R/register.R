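# Registration engine: sampled metric evaluation with analytic parameter
# gradients, adaptive stochastic gradient descent, and the multiresolution
# driver. The four framework legs are: transform (transforms.R), metric
# (metrics.R), interpolator (volume.R / src), optimizer (this file).

# ---- precomputed per-level state -------------------------------------------

# linear-index array selecting slices `sel` along axis `a`
slice_index <- function(d, a, sel) {
  args <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  args[[a]] <- sel
  idx <- array(seq_len(prod(d)), d)
  do.call(`[`, c(list(idx), args))
}

metric_state <- function(fixed, moving, cfg, mask = NULL, jitter = FALSE) {
  if (is.null(mask)) mask <- cfg$fixed_mask
  d <- dim(fixed$values)
  if (is.null(mask)) {
    keep <- seq_len(prod(d))
  } else {
    stopifnot(all(dim(mask) == d))
    keep <- which(as.logical(mask))
    if (!length(keep)) stop("empty sample set: mask excludes everything")
  }
  idx0 <- cbind((keep - 1) %% d[1],
                ((keep - 1) %/% d[1]) %% d[2],
                (keep - 1) %/% (d[1] * d[2]))
  if (jitter) {
    # off-grid sampling: node-aligned samples with commensurate fixed and
    # moving spacings produce the well-known grid-artifact bias of
    # interpolation-based mutual information; a sub-voxel jitter of the
    # sample positions (drawn once per state under the seeded RNG)
    # removes it
    idx0 <- idx0 + matrix(runif(length(idx0), -0.5, 0.5), nrow(idx0), 3)
    idx0 <- pmin(pmax(idx0, 0), matrix(rep(d - 1, each = nrow(idx0)),
                                       nrow(idx0), 3))
    fvals <- cpp_interp3(as.numeric(fixed$values), d, idx0, 1L, cfg$fill)
  } else {
    fvals <- as.numeric(fixed$values)[keep]
  }
  fpts <- index_to_world(fixed, idx0)
  list(fpts = fpts, fvals = fvals, n = length(keep),
       frange = range(fvals),
       m_values = as.numeric(moving$values), m_dim = dim(moving$values),
       m_origin = moving$origin, m_spacing = moving$spacing,
       m_dir = moving$direction,
       mrange = range(moving$values),
       fill = cfg$fill)
}

sample_points <- function(st, samples, cfg) {
  if (identical(samples, "all") || is.null(samples)) return(seq_len(st$n))
  sample.int(st$n, min(as.integer(samples), st$n))
}

moving_index <- function(st, y) {
  rel <- sweep(y, 2, st$m_origin) %*% st$m_dir
  sweep(rel, 2, st$m_spacing, "/")
}

# ---- transform parameterization --------------------------------------------

# tinfo: list(model, center, outer [affine3 or NULL], grid [bspline geometry])
tinfo_from_transform <- function(t, model = NULL) {
  if (inherits(t, "composite3") && length(t$components) == 2L &&
      inherits(t$components[[1]], "bspline3") &&
      is_linear3(t$components[[2]])) {
    bs <- t$components[[1]]
    return(list(model = "bspline", outer = t$components[[2]],
                grid = list(origin = bs$grid_origin,
                            spacing = bs$grid_spacing,
                            shape = dim(bs$coef)[1:3])))
  }
  if (inherits(t, "rigid3")) list(model = "rigid", center = t$center)
  else if (inherits(t, "similarity3")) list(model = "similarity", center = t$center)
  else if (inherits(t, "affine3")) list(model = "affine", center = t$center)
  else stop("cannot parameterize transform of class ", class(t)[1])
}

params_from_transform <- function(t, tinfo) {
  switch(tinfo$model,
    rigid = c(t$angles, t$translation),
    similarity = c(t$angles, t$translation, t$scale),
    affine = c(as.numeric(t$matrix), t$translation),
    bspline = as.numeric(t$components[[1]]$coef))
}

transform_from_params <- function(p, tinfo) {
  switch(tinfo$model,
    rigid = rigid3(p[1:3], p[4:6], tinfo$center),
    similarity = similarity3(p[1:3], p[4:6], tinfo$center, max(p[7], 1e-6)),
    affine = affine3(matrix(p[1:9], 3, 3), p[10:12], tinfo$center),
    bspline = composite_transform(
      bspline3(tinfo$grid$origin, tinfo$grid$spacing,
               array(p, c(tinfo$grid$shape, 3L))),
      tinfo$outer))
}

param_scales <- function(tinfo, radius) {
  switch(tinfo$model,
    rigid = c(rep(radius, 3), rep(1, 3)),
    similarity = c(rep(radius, 3), rep(1, 3), radius),
    affine = c(rep(radius, 9), rep(1, 3)),
    bspline = rep(1, 3 * prod(tinfo$grid$shape)))
}

# derivatives of R = Rx(a) Ry(b) Rz(c) with respect to each angle
euler_deriv <- function(ang) {
  a <- ang[1]; b <- ang[2]; c_ <- ang[3]
  dRx <- matrix(c(0, 0, 0, 0, -sin(a), cos(a), 0, -cos(a), -sin(a)), 3, 3)
  dRy <- matrix(c(-sin(b), 0, -cos(b), 0, 0, 0, cos(b), 0, -sin(b)), 3, 3)
  dRz <- matrix(c(-sin(c_), cos(c_), 0, -cos(c_), -sin(c_), 0, 0, 0, 0), 3, 3)
  list(dRx %*% rot_y(b) %*% rot_z(c_),
       rot_x(a) %*% dRy %*% rot_z(c_),
       rot_x(a) %*% rot_y(b) %*% dRz)
}

# ---- sampled metric value and parameter gradient ---------------------------

metric_samples_eval <- function(st, tinfo, p, pick, cfg, want_grad = FALSE,
                                penalty = FALSE) {
  x <- st$fpts[pick, , drop = FALSE]
  f <- st$fvals[pick]
  model <- tinfo$model
  if (model == "bspline") {
    bs_coef <- p
    disp <- cpp_bspline_disp(bs_coef, tinfo$grid$shape, tinfo$grid$origin,
                             tinfo$grid$spacing, x)
    inner <- x + disp
    md <- linear_md(tinfo$outer)
    y <- sweep(inner %*% t(md$M), 2, md$d, "+")
  } else {
    ang <- p[1:3]
    R <- euler_to_matrix(ang)
    M <- switch(model, rigid = R, similarity = p[7] * R,
                affine = matrix(p[1:9], 3, 3))
    tr <- switch(model, rigid = p[4:6], similarity = p[4:6], affine = p[10:12])
    xc <- sweep(x, 2, tinfo$center)
    y <- sweep(xc %*% t(M), 2, tinfo$center + tr, "+")
  }
  idx <- moving_index(st, y)
  dmax <- st$m_dim - 1
  inside <- idx[, 1] >= 0 & idx[, 2] >= 0 & idx[, 3] >= 0 &
    idx[, 1] <= dmax[1] & idx[, 2] <= dmax[2] & idx[, 3] <= dmax[3]
  frac <- mean(inside)
  if (frac < 0.05) {
    if (penalty) {
      # line searches may probe far-off parameters; return a finite penalty
      out <- list(value = 1e6, n = 0L, inside_fraction = frac)
      if (want_grad) out$grad <- rep(0, length(p))
      return(out)
    }
    if (!any(inside))
      stop("no fixed samples map inside the moving image; ",
           "the initialization (reference plane) is the likely cause")
  }
  # all samples take part: out-of-domain points contribute the fill value
  # (zero gradient), so the optimizer cannot gain by expelling samples from
  # the overlap region
  fi <- f
  if (want_grad) {
    vg <- cpp_interp3_grad(st$m_values, st$m_dim, idx, st$fill)
    m <- vg[, 1]
  } else {
    m <- cpp_interp3(st$m_values, st$m_dim, idx, 1L, st$fill)
  }
  mv <- switch(cfg$metric,
    mutual_information = mi_from_samples(fi, m, st$frange, st$mrange,
                                         cfg$histogram_bins, want_grad),
    normalized_correlation = ncc_from_samples(fi, m, want_grad),
    mean_squared_difference = msd_from_samples(fi, m, want_grad))
  out <- list(value = mv$value, n = mv$n, inside_fraction = frac,
              mi = mv$mi)
  if (!want_grad) return(out)
  # exact gradient of the trilinear interpolant, mapped to world coordinates
  gw <- sweep(vg[, 2:4, drop = FALSE], 2, st$m_spacing, "/") %*% t(st$m_dir)
  dCdy <- mv$dm * gw
  if (model == "bspline") {
    md <- linear_md(tinfo$outer)
    dInner <- dCdy %*% md$M # row-wise t(M) %*% dCdy
    out$grad <- as.numeric(
      cpp_bspline_grad_accum(tinfo$grid$shape, tinfo$grid$origin,
                             tinfo$grid$spacing, x, dInner))
  } else {
    xc_in <- sweep(x, 2, tinfo$center)
    gt <- colSums(dCdy)
    if (model == "affine") {
      gM <- crossprod(dCdy, xc_in) # 3x3, gM[a,b] = sum dCdy[,a] * xc[,b]
      out$grad <- c(as.numeric(gM), gt)
    } else {
      dR <- euler_deriv(p[1:3])
      sc <- if (model == "similarity") p[7] else 1
      ga <- vapply(dR, function(D) sum(dCdy * (xc_in %*% t(D))) * sc, 0)
      if (model == "similarity") {
        R <- euler_to_matrix(p[1:3])
        gs <- sum(dCdy * (xc_in %*% t(R)))
        out$grad <- c(ga, gt, gs)
      } else out$grad <- c(ga, gt)
    }
  }
  out
}

# ---- single-level optimizer -------------------------------------------------

#' Optimize a transform at a single resolution
#'
#' Adaptive stochastic gradient descent with a decaying step size
#' \code{a/(A+k)^alpha}: each iteration draws a fresh random set of fixed
#' samples (seeded), evaluates the metric and its analytic parameter
#' gradient, and takes a step. The gain \code{a} is auto-scaled from an
#' initial gradient probe so the first step displaces points about one voxel.
#' For low-DOF models a deterministic BFGS refinement on a fixed sample set
#' follows (\code{cfg$refine}). If the final full-sample metric is worse than
#' at \code{t0}, \code{t0} is returned unchanged.
#'
#' @param fixed,moving \code{\link{volume_image}}s at one resolution level.
#' @param t0 initial transform (a \code{rigid3}, \code{similarity3},
#'   \code{affine3}, or a composite of a \code{bspline3} followed by a linear
#'   transform).
#' @param cfg a \code{\link{registration_config}}.
#' @param mask optional logical array on the fixed grid (overrides
#'   \code{cfg$fixed_mask}).
#' @param refine run the deterministic refinement (default: config value).
#' @param check_full verify the full-sample metric did not get worse and
#'   revert to \code{t0} if it did.
#' @return the optimized transform; attributes \code{metric_value} and
#'   \code{metric_initial} hold full-sample cost values.
#' @export
optimize_transform <- function(fixed, moving, t0, cfg = registration_config(),
                               mask = NULL, refine = NULL, check_full = TRUE) {
  st <- metric_state(fixed, moving, cfg, mask, jitter = cfg$sample_jitter)
  tinfo <- tinfo_from_transform(t0)
  if (is.null(tinfo$center)) tinfo$center <- grid_center(fixed)
  p <- params_from_transform(t0, tinfo)
  ext <- (dim(fixed$values) - 1) * fixed$spacing
  radius <- 0.5 * sqrt(sum(ext^2))
  s <- param_scales(tinfo, radius)
  delta0 <- max(fixed$spacing)
  alpha <- cfg$step_alpha; A <- cfg$step_A
  iters <- cfg$iterations_per_level

  if (iters > 0) {
    gmax <- 0
    for (j in 1:3) {
      pick <- sample_points(st, cfg$samples_per_iteration, cfg)
      ev <- metric_samples_eval(st, tinfo, p, pick, cfg, want_grad = TRUE,
                                penalty = TRUE)
      gmax <- max(gmax, max(abs(ev$grad / s)))
    }
    a <- if (!is.null(cfg$step_a)) cfg$step_a
         else delta0 * (A + 1)^alpha / max(gmax, 1e-12)
    for (k in seq_len(iters)) {
      pick <- sample_points(st, cfg$samples_per_iteration, cfg)
      ev <- metric_samples_eval(st, tinfo, p, pick, cfg, want_grad = TRUE,
                                penalty = TRUE)
      if (!all(is.finite(ev$grad)) || !is.finite(ev$value))
        stop("non-finite metric or gradient at iteration ", k,
             " (value = ", ev$value, ")")
      p <- p - (a / (A + k)^alpha) * (ev$grad / s^2)
    }
  }

  do_refine <- if (is.null(refine)) cfg$refine else isTRUE(refine)
  if (do_refine) {
    pick <- sample_points(st, max(cfg$refine_samples,
                                  cfg$samples_per_iteration), cfg)
    fn <- function(q) metric_samples_eval(st, tinfo, q / s, pick, cfg,
                                          penalty = TRUE)$value
    gr <- function(q) metric_samples_eval(st, tinfo, q / s, pick, cfg,
                                          want_grad = TRUE,
                                          penalty = TRUE)$grad / s
    # low-DOF models use BFGS; the high-dimensional B-spline stage uses
    # L-BFGS-B, which removes the stochastic-descent noise floor from the
    # deformation coefficients
    meth <- if (tinfo$model == "bspline") "L-BFGS-B" else "BFGS"
    ctrl <- if (meth == "BFGS")
      list(maxit = cfg$refine_maxit, reltol = 1e-12)
    else list(maxit = cfg$refine_maxit, factr = 1e4)
    full_of <- function(q)
      metric_samples_eval(st, tinfo, q, seq_len(st$n), cfg,
                          penalty = TRUE)$value
    # the stochastic search occasionally wanders off; refine from both its
    # endpoint and the stage initialization and keep the better full-sample
    # optimum
    p0 <- params_from_transform(t0, tinfo)
    starts <- list(p)
    if (full_of(p0) < full_of(p)) starts <- c(starts, list(p0))
    best_p <- p
    best_v <- full_of(p)
    for (pst in starts) {
      opt <- stats::optim(pst * s, fn, gr, method = meth, control = ctrl)
      p_ref <- opt$par / s
      v_ref <- full_of(p_ref)
      if (v_ref < best_v) {
        best_p <- p_ref
        best_v <- v_ref
      }
    }
    p <- best_p
  }

  out <- transform_from_params(p, tinfo)
  if (check_full) {
    all_pick <- seq_len(st$n)
    p0 <- params_from_transform(t0, tinfo)
    v0 <- metric_samples_eval(st, tinfo, p0, all_pick, cfg,
                              penalty = TRUE)$value
    v1 <- metric_samples_eval(st, tinfo, p, all_pick, cfg,
                              penalty = TRUE)$value
    if (v1 > v0) {
      out <- t0
      v1 <- v0
    }
    attr(out, "metric_value") <- v1
    attr(out, "metric_initial") <- v0
  }
  out
}

# ---- multiresolution registration driver -----------------------------------

usable_factors <- function(cfg, ...) {
  dims <- list(...)
  keep <- vapply(seq_along(cfg$pyramid_factors), function(i) {
    f <- cfg$pyramid_factors[i]
    if (f == 1) return(TRUE)
    all(vapply(dims, function(d) all(floor((d - 1) / f) + 1 >= 4), TRUE))
  }, TRUE)
  if (!all(keep))
    warning("pyramid levels skipped: image smaller than coarsest factor")
  keep
}

bspline_grid_for <- function(fixed, spacing) {
  d <- dim(fixed$values)
  corners <- as.matrix(expand.grid(c(0, d[1] - 1), c(0, d[2] - 1),
                                   c(0, d[3] - 1)))
  w <- index_to_world(fixed, corners)
  lo <- apply(w, 2, min); hi <- apply(w, 2, max)
  spacing <- rep(spacing, length.out = 3)
  n_int <- pmax(1, ceiling((hi - lo) / spacing))
  # one control point margin on each side of the covered domain
  shape <- n_int + 1 + 2
  origin <- lo - spacing
  list(origin = origin, spacing = spacing, shape = as.integer(shape))
}

#' Intensity-based registration of two volumes
#'
#' Multiresolution registration of \code{moving} to \code{fixed} for one
#' transform model, initialized at \code{init}. Runs
#' \code{\link{build_pyramid}} and \code{\link{optimize_transform}} per
#' level. The returned transform maps fixed world points into the moving
#' world frame (pull-back convention). The \code{bspline} model optimizes a
#' free-form deformation applied before the initializing linear transform:
#' \code{x -> T_linear(x + D(x))}, with the control grid covering the fixed
#' domain plus a one-control-point margin.
#'
#' @param fixed,moving \code{\link{volume_image}}s.
#' @param model transform model with gradually increasing degrees of freedom.
#' @param cfg a \code{\link{registration_config}}.
#' @param init initial transform, typically the previous stage's result
#'   (default: identity about the fixed-image center).
#' @return the optimized transform, with attributes \code{metric_value} /
#'   \code{metric_initial} (full-sample cost at the finest level).
#' @export
register <- function(fixed, moving,
                     model = c("rigid", "similarity", "affine", "bspline"),
                     cfg = registration_config(), init = NULL) {
  model <- match.arg(model)
  set.seed(cfg$seed)
  center <- if (!is.null(init) && !is.null(init$center)) init$center
            else grid_center(fixed)
  if (is.null(init)) init <- rigid3(center = center)

  t_cur <- promote_transform(init, model, center, cfg, fixed)
  keep <- usable_factors(cfg, dim(fixed$values), dim(moving$values))
  cfg_lv <- cfg
  cfg_lv$pyramid_factors <- cfg$pyramid_factors[keep]
  cfg_lv$pyramid_smooth <- cfg$pyramid_smooth[keep]
  # coarse levels whose masked sample count is too small for a stable joint
  # histogram are skipped (the reference-plane initialization already
  # provides the coarse alignment they would otherwise supply)
  if (!is.null(cfg$fixed_mask)) {
    counts <- vapply(build_mask_pyramid(cfg$fixed_mask,
                                        cfg_lv$pyramid_factors),
                     function(m) if (is.null(m)) 0L else sum(m), 0L)
    enough <- counts >= cfg$min_level_samples |
      seq_along(counts) == length(counts)
    cfg_lv$pyramid_factors <- cfg_lv$pyramid_factors[enough]
    cfg_lv$pyramid_smooth <- cfg_lv$pyramid_smooth[enough]
  }
  fpyr <- build_pyramid(fixed, cfg_lv)
  mpyr <- build_pyramid(moving, cfg_lv)
  mask_pyr <- if (!is.null(cfg$fixed_mask))
    build_mask_pyramid(cfg$fixed_mask, cfg_lv$pyramid_factors) else NULL

  # overlap precondition at the initialization
  st0 <- metric_state(fpyr[[1]], mpyr[[1]], cfg,
                      if (!is.null(mask_pyr)) mask_pyr[[1]] else NULL)
  ti0 <- tinfo_from_transform(t_cur)
  if (is.null(ti0$center)) ti0$center <- center
  ev0 <- metric_samples_eval(st0, ti0, params_from_transform(t_cur, ti0),
                             seq_len(st0$n), cfg)
  if (ev0$inside_fraction < cfg$min_overlap)
    stop(sprintf(paste0("insufficient overlap (%.0f%% of fixed samples map ",
                        "inside the moving image); the initialization ",
                        "(reference plane / center alignment) is the likely ",
                        "cause"), 100 * ev0$inside_fraction))

  nlev <- length(fpyr)
  t_init <- t_cur
  for (l in seq_len(nlev)) {
    t_cur <- optimize_transform(fpyr[[l]], mpyr[[l]], t_cur, cfg,
                                mask = if (!is.null(mask_pyr)) mask_pyr[[l]] else NULL,
                                refine = cfg$refine && l == nlev,
                                check_full = (l == nlev))
  }
  # safety net: if the whole multiresolution run ended up worse than the
  # stage initialization on a full-sample evaluation, keep the initialization
  ti <- tinfo_from_transform(t_init)
  if (is.null(ti$center)) ti$center <- center
  stf <- metric_state(fpyr[[nlev]], mpyr[[nlev]], cfg,
                      if (!is.null(mask_pyr)) mask_pyr[[nlev]] else NULL)
  v_init <- metric_samples_eval(stf, ti, params_from_transform(t_init, ti),
                                seq_len(stf$n), cfg, penalty = TRUE)$value
  if (is.null(attr(t_cur, "metric_value")) ||
      attr(t_cur, "metric_value") > v_init) {
    attr(t_init, "metric_value") <- v_init
    attr(t_init, "metric_initial") <- v_init
    t_cur <- t_init
  } else {
    attr(t_cur, "metric_initial") <- v_init
  }
  t_cur
}

# convert the previous stage's transform into an initial transform of the
# requested model
promote_transform <- function(init, model, center, cfg, fixed) {
  if (model == "bspline") {
    if (inherits(init, "composite3")) return(init)
    stopifnot(is_linear3(init))
    g <- bspline_grid_for(fixed, cfg$bspline_spacing)
    return(composite_transform(
      bspline3(g$origin, g$spacing, array(0, c(g$shape, 3L))), init))
  }
  if (inherits(init, "composite3"))
    stop("cannot initialize a linear model from a composite transform")
  stopifnot(is_linear3(init))
  md <- linear_md(init)
  tr_about <- function(cen) as.numeric(md$M %*% cen + md$d) - cen
  if (model == "rigid") {
    if (inherits(init, "rigid3")) return(init)
    ang <- matrix_to_euler(md$M / det(md$M)^(1 / 3))
    rigid3(ang, tr_about(center), center)
  } else if (model == "similarity") {
    sc <- det(md$M)^(1 / 3)
    ang <- if (inherits(init, "affine3")) matrix_to_euler(md$M / sc)
           else init$angles
    similarity3(ang, tr_about(center), center,
                if (inherits(init, "similarity3")) init$scale else max(sc, 1e-6))
  } else { # affine
    affine3(md$M, tr_about(center), center)
  }
}
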