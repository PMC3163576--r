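# Serial-section stacking: iterative 2D rigid alignment of adjacent sections
# and reconstruction of the 3D color histology volume.

# bilinear/nearest interpolation of a 2D image at mm coordinates (pixel
# spacing px, pixel (0,0) at (0,0) mm)
interp2_mm <- function(img, pts_mm, px, scheme = 1L, fill = 0) {
  idx <- pts_mm / px
  cpp_interp2(as.numeric(img), dim(img), idx, scheme, fill)
}

grid_points_2d <- function(d, px) {
  cbind(rep.int(seq_len(d[1]) - 1, d[2]),
        rep(seq_len(d[2]) - 1, each = d[1])) * px
}

resample_2d <- function(img, t2, px, scheme = 1L, fill = 0) {
  pts <- apply_transform(t2, grid_points_2d(dim(img), px))
  matrix(interp2_mm(img, pts, px, scheme, fill), dim(img)[1], dim(img)[2])
}

# Deterministic 2D rigid registration (Nelder-Mead then BFGS polish) on the
# normalized-correlation cost; 3 DOF, full overlap sampling. Mono-modal by
# design: adjacent H&E sections share contrast, so correlation is the
# appropriate metric and a derivative-free local search converges reliably.
register_rigid2d <- function(fixed, moving, px, init = rigid2(),
                             metric = c("normalized_correlation",
                                        "mean_squared_difference"),
                             sample_stride = 1L) {
  register_rigid2d_impl(fixed, moving, px, init, match.arg(metric),
                        sample_stride)
}

register_rigid2d_impl <- function(fixed, moving, px, init, metric,
                                  sample_stride) {
  center <- (dim(fixed)[1:2] - 1) / 2 * px
  d <- dim(fixed)
  pts <- grid_points_2d(d, px)
  fvals <- as.numeric(fixed)
  if (sample_stride > 1L) {
    keep <- seq(1, nrow(pts), by = sample_stride)
    pts <- pts[keep, , drop = FALSE]
    fvals <- fvals[keep]
  }
  cost <- function(p) {
    t2 <- rigid2(p[1], p[2:3], center)
    y <- apply_transform(t2, pts)
    m <- interp2_mm(moving, y, px, 1L, NA_real_)
    ok <- !is.na(m)
    if (mean(ok) < 0.2) return(1)
    f <- fvals[ok]; mm <- m[ok]
    if (metric == "normalized_correlation") {
      if (sd(f) == 0 || sd(mm) == 0) return(1)
      -abs(cor(f, mm))
    } else mean((mm - f)^2)
  }
  p0 <- c(init$angle, init$translation)
  o1 <- stats::optim(p0, cost, method = "Nelder-Mead",
                     control = list(maxit = 400, reltol = 1e-10))
  o2 <- stats::optim(o1$par, cost, method = "BFGS",
                     control = list(maxit = 100, reltol = 1e-12,
                                    ndeps = rep(1e-5, 3)))
  best <- if (o2$value <= o1$value) o2 else o1
  out <- rigid2(best$par[1], best$par[2:3], center)
  attr(out, "metric_value") <- best$value
  out
}

# binary erosion of a 2D mask (4-connectivity)
erode2d <- function(mask, iterations) {
  d <- dim(mask)
  for (i in seq_len(iterations)) {
    sh <- mask
    sh[-1, ] <- sh[-1, ] & mask[-d[1], ]
    sh[-d[1], ] <- sh[-d[1], ] & mask[-1, ]
    sh[, -1] <- sh[, -1] & mask[, -d[2]]
    sh[, -d[2]] <- sh[, -d[2]] & mask[, -1]
    mask <- sh
  }
  mask
}

# Refine a pairwise rigid transform on the eroded tissue interior. Adjacent
# sections differ not only by slice jitter but also by the slow evolution of
# the specimen's outline (cross-sections grow and shrink); that boundary
# flow biases a whole-image fit. The tissue interior shared by neighbouring
# sections carries stable structure, so a refinement restricted to it
# recovers the rigid jitter without the boundary bias; the whole-image
# stage supplies the capture range.
refine_rigid2d_interior <- function(fixed, moving, px, init,
                                    erode_px = 3L, min_pixels = 200L) {
  d <- dim(fixed)
  tis <- erode2d(fixed < 0.92 * max(fixed), erode_px)
  idx <- which(tis)
  if (length(idx) < min_pixels) return(init)
  center <- init$center
  pts <- grid_points_2d(d, px)[idx, , drop = FALSE]
  fv <- as.numeric(fixed)[idx]
  cost <- function(p) {
    y <- apply_transform(rigid2(p[1], p[2:3], center), pts)
    m <- interp2_mm(moving, y, px, 1L, NA_real_)
    ok <- !is.na(m)
    if (mean(ok) < 0.5 || sd(m[ok]) == 0) return(1)
    -abs(cor(fv[ok], m[ok]))
  }
  p0 <- c(init$angle, init$translation)
  o1 <- stats::optim(p0, cost, method = "Nelder-Mead",
                     control = list(maxit = 300, reltol = 1e-11))
  o2 <- stats::optim(o1$par, cost, method = "BFGS",
                     control = list(maxit = 80, reltol = 1e-12,
                                    ndeps = rep(1e-5, 3)))
  p <- (if (o2$value <= o1$value) o2 else o1)$par
  if (max(abs(p - p0)) > 2.5 * px) return(init) # left the capture basin
  out <- rigid2(p[1], p[2:3], center)
  attr(out, "metric_value") <- attr(init, "metric_value")
  out
}

# analytic composition of 2D rigid transforms about a shared center:
# point -> inner -> outer
compose_rigid2 <- function(outer, inner) {
  th <- outer$angle
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rigid2(outer$angle + inner$angle,
         outer$translation + as.numeric(R %*% inner$translation),
         outer$center)
}

#' Reconstruct a 3D histology volume by stacking 2D sections
#'
#' Registers the driver-channel image of each section rigidly (2D) to its
#' already-aligned predecessor, accumulating transforms outward from the
#' anchor (section 1, the reference cutting plane, which keeps the identity
#' transform). The pairwise alignment runs in two stages: a whole-image
#' normalized-correlation fit for capture, then a refinement restricted to
#' the eroded tissue interior, which is insensitive to the slow evolution
#' of the specimen outline across sections. The alignment to the aligned
#' predecessor is realized by registering adjacent raw sections and
#' concatenating the rigid transforms analytically, so no interpolation
#' error accumulates along the chain. The recovered transforms are applied
#' to all three color channels and the result is stacked with slice spacing
#' equal to the physical section interval (80 um by default acquisition).
#'
#' @param stack a \code{\link{section_stack}} (at least 2 sections).
#' @param cfg a \code{\link{registration_config}}; only the metric choice is
#'   used by the 2D stage (normalized correlation by default).
#' @param driver_channel channel used to drive the registration (red by
#'   default; see \code{\link{select_registration_channel}}).
#' @param fail_threshold a section whose final cost exceeds this value (for
#'   correlation: |r| below the magnitude) is flagged as failed; the identity
#'   transform is used and a warning logged.
#' @return an object of class \code{stacking_result}: \code{channels} (list
#'   of three \code{\link{volume_image}}s), \code{per_slice_transforms}
#'   (list of \code{\link{rigid2}}), \code{driver_channel}, and
#'   \code{metrics} (final per-slice cost values).
#' @export
stack_sections <- function(stack, cfg = registration_config(
                             metric = "normalized_correlation"),
                           driver_channel = "red", fail_threshold = -0.2) {
  n <- length(stack$sections)
  if (n < 2) stop("stacking requires >= 2 sections")
  px <- stack$pixel_size
  driver <- extract_channel(stack, driver_channel)
  transforms <- vector("list", n)
  metrics <- rep(NA_real_, n)
  center <- (dim(driver[[1]])[1:2] - 1) / 2 * px
  transforms[[1]] <- rigid2(center = center)
  metric2d <- if (cfg$metric == "mean_squared_difference")
    "mean_squared_difference" else "normalized_correlation"
  for (i in 2:n) {
    delta <- register_rigid2d(driver[[i - 1]], driver[[i]], px,
                              metric = metric2d)
    v <- attr(delta, "metric_value")
    if (v > fail_threshold) {
      warning(sprintf("section %d: registration failed (cost %.3f); %s",
                      i, v, "identity transform used"))
      delta <- rigid2(center = center)
      v <- NA_real_
    } else if (metric2d == "normalized_correlation") {
      delta <- refine_rigid2d_interior(driver[[i - 1]], driver[[i]], px,
                                       delta)
    }
    transforms[[i]] <- compose_rigid2(delta, transforms[[i - 1]])
    metrics[i] <- v
  }
  d <- dim(driver[[1]])
  channels <- lapply(c("red", "green", "blue"), function(ch) {
    imgs <- extract_channel(stack, ch)
    vol <- array(0, c(d[1], d[2], n))
    for (i in seq_len(n))
      vol[, , i] <- resample_2d(imgs[[i]], transforms[[i]], px,
                                fill = stats::median(imgs[[i]]))
    volume_image(vol, spacing = c(px, px, stack$interval),
                 origin = c(0, 0, 0))
  })
  names(channels) <- c("red", "green", "blue")
  structure(list(channels = channels, per_slice_transforms = transforms,
                 driver_channel = driver_channel, metrics = metrics,
                 pixel_size = px, interval = stack$interval),
            class = "stacking_result")
}

#' @export
print.stacking_result <- function(x, ...) {
  d <- dim(x$channels[[1]]$values)
  cat(sprintf("<stacking_result> %d x %d x %d color stack (driver: %s)\n",
              d[1], d[2], d[3], x$driver_channel))
  invisible(x)
}

#' Select the color channel separating necrotic from viable tissue best
#'
#' Scores each channel by the separability of the intensity histograms of a
#' necrotic and a viable region annotated on one section: score =
#' 1 - Bhattacharyya overlap of the normalized 64-bin histograms. Returns the
#' channel with the strictly greatest score; ties break toward red. On
#' H&E-stained material this selects the red channel.
#'
#' @param stack a \code{\link{section_stack}}.
#' @param necrotic_voi,viable_voi logical 2D masks on the annotated section.
#' @param section index of the annotated section.
#' @param bins histogram bins.
#' @return list with \code{channel} and named \code{scores}.
#' @export
select_registration_channel <- function(stack, necrotic_voi, viable_voi,
                                        section = 1, bins = 64) {
  if (!any(necrotic_voi) || !any(viable_voi))
    stop("empty VOI: both necrotic and viable masks must be non-empty")
  img <- stack$sections[[section]]
  scores <- vapply(1:3, function(ci) {
    a <- img[, , ci][necrotic_voi]
    b <- img[, , ci][viable_voi]
    histogram_separability(a, b, bins)
  }, 0)
  names(scores) <- c("red", "green", "blue")
  list(channel = names(scores)[which.max(scores)], scores = scores)
}

# 1 - Bhattacharyya coefficient of two normalized histograms on a shared grid
histogram_separability <- function(a, b, bins = 64) {
  r <- range(c(a, b))
  if (r[1] == r[2]) return(0)
  br <- seq(r[1], r[2], length.out = bins + 1)
  pa <- tabulate(pmin(findInterval(a, br, all.inside = TRUE), bins), bins)
  pb <- tabulate(pmin(findInterval(b, br, all.inside = TRUE), bins), bins)
  pa <- pa / sum(pa); pb <- pb / sum(pb)
  1 - sum(sqrt(pa * pb))
}
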