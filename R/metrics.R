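#' Registration configuration
#'
#' Bundles every constant of the registration engine: similarity metric,
#' joint-histogram size, stochastic sampling, multiresolution pyramid,
#' step-size schedule of the stochastic gradient descent, and the random
#' seed. A fixed seed makes a run fully reproducible.
#'
#' @param metric similarity metric; mutual information for inter-modality
#'   steps, normalized correlation for mono-modal stacking.
#' @param histogram_bins joint-histogram bins per image (>= 8).
#' @param samples_per_iteration random fixed-image samples drawn per
#'   iteration of the stochastic optimizer.
#' @param pyramid_factors per-level downsampling factors, coarse to fine
#'   (finest must be 1).
#' @param pyramid_smooth per-level Gaussian smoothing widths (voxels).
#' @param iterations_per_level stochastic gradient descent iterations per
#'   pyramid level.
#' @param step_alpha,step_A decay of the step size \code{a/(A+k)^alpha}.
#' @param step_a gain \code{a}; \code{NULL} auto-scales it from an initial
#'   gradient probe so the first step moves points about one voxel.
#' @param seed integer random seed.
#' @param fixed_mask optional logical array on the fixed grid restricting
#'   sampling (e.g. a tumor mask).
#' @param refine run a deterministic BFGS refinement on a fixed sample set at
#'   the finest level (low-DOF models only).
#' @param refine_samples,refine_maxit refinement sample budget (capped at
#'   the masked voxel count; the default effectively uses every masked
#'   voxel, making the refinement optimum well defined) and iterations.
#' @param bspline_spacing control-point spacing (mm) of the elastic stage.
#' @param min_overlap minimum fraction of fixed samples that must map inside
#'   the moving image under the initialization.
#' @param min_level_samples pyramid levels with fewer masked fixed samples
#'   than this are skipped (the finest level always runs).
#' @param sample_jitter draw sample positions off-grid (sub-voxel uniform
#'   jitter) instead of at voxel nodes.
#' @param fill out-of-domain intensity fill value.
#' @return a list of class \code{registration_config}.
#' @export
registration_config <- function(metric = c("mutual_information",
                                           "normalized_correlation",
                                           "mean_squared_difference"),
                                histogram_bins = 32,
                                samples_per_iteration = 2048,
                                pyramid_factors = c(4, 2, 1),
                                pyramid_smooth = c(2, 1, 0),
                                iterations_per_level = 500,
                                step_alpha = 0.602,
                                step_A = 50,
                                step_a = NULL,
                                seed = 1,
                                fixed_mask = NULL,
                                refine = TRUE,
                                refine_samples = 100000,
                                refine_maxit = 100,
                                bspline_spacing = 3.2,
                                min_overlap = 0.1,
                                min_level_samples = 1000,
                                sample_jitter = FALSE,
                                fill = 0) {
  metric <- match.arg(metric)
  stopifnot(histogram_bins >= 8, length(pyramid_factors) >= 1,
            length(pyramid_factors) == length(pyramid_smooth),
            pyramid_factors[length(pyramid_factors)] == 1,
            iterations_per_level >= 0)
  structure(list(metric = metric, histogram_bins = as.integer(histogram_bins),
                 samples_per_iteration = as.integer(samples_per_iteration),
                 pyramid_factors = as.integer(pyramid_factors),
                 pyramid_smooth = as.numeric(pyramid_smooth),
                 iterations_per_level = as.integer(iterations_per_level),
                 step_alpha = step_alpha, step_A = step_A, step_a = step_a,
                 seed = as.integer(seed), fixed_mask = fixed_mask,
                 refine = isTRUE(refine),
                 refine_samples = as.integer(refine_samples),
                 refine_maxit = as.integer(refine_maxit),
                 bspline_spacing = bspline_spacing,
                 min_overlap = min_overlap,
                 min_level_samples = as.integer(min_level_samples),
                 sample_jitter = isTRUE(sample_jitter),
                 fill = fill),
            class = "registration_config")
}

# ---- histogram / metric kernels --------------------------------------------

# weighted 2D histogram with linear (partial-volume) binning; f, m numeric
# vectors already scaled to continuous bin coordinates in [0, nb-1]
pv_joint_hist <- function(uf, um, nb) {
  f0 <- pmin(floor(uf), nb - 2); wf <- uf - f0
  m0 <- pmin(floor(um), nb - 2); wm <- um - m0
  i00 <- f0 + nb * m0 + 1
  idx <- c(i00, i00 + 1, i00 + nb, i00 + nb + 1)
  w <- c((1 - wf) * (1 - wm), wf * (1 - wm), (1 - wf) * wm, wf * wm)
  W <- numeric(nb * nb)
  s <- rowsum(w, idx)
  W[as.integer(rownames(s))] <- s
  matrix(W, nb, nb)
}

to_bin_coord <- function(x, range, nb) {
  w <- range[2] - range[1]
  if (w <= 0) stop("degenerate image: fewer than 2 distinct intensities in ",
                   "the sampled region")
  pmin(pmax((x - range[1]) / w * (nb - 1), 0), nb - 1)
}

# histogram size adapted to the sample count: a joint histogram with many
# more cells than samples makes the MI estimate degenerate, so small sample
# sets (coarse pyramid levels of masked problems) use fewer bins
adapt_bins <- function(nb, n) {
  min(nb, max(8L, 2L^floor(log2(sqrt(n / 4)))))
}

# Mutual information (bits) of paired samples, with optional derivative of
# the cost (-MI) with respect to the moving intensities.
mi_from_samples <- function(f, m, frange, mrange, nb, want_dm = FALSE) {
  n <- length(f)
  if (n == 0) stop("empty sample set: mask excludes everything")
  nb <- adapt_bins(nb, n)
  uf <- to_bin_coord(f, frange, nb)
  um <- to_bin_coord(m, mrange, nb)
  W <- pv_joint_hist(uf, um, nb)
  p <- W / n
  pf <- rowSums(p); pm <- colSums(p)
  pos <- p > 0
  mi <- sum(p[pos] * log2(p[pos] / (pf[row(p)[pos]] * pm[col(p)[pos]])))
  out <- list(value = -mi, mi = max(mi, 0), n = n)
  if (want_dm) {
    eps <- 1e-12
    L <- log(pmax(p, eps)) -
      log(pmax(pf, eps))[row(p)] - log(pmax(pm, eps))[col(p)]
    dim(L) <- c(nb, nb)
    f0 <- pmin(floor(uf), nb - 2); wf <- uf - f0
    m0 <- pmin(floor(um), nb - 2)
    # d MI / d um (natural log), zero where the moving sample was clamped
    at <- function(fi, mi_) L[fi + nb * mi_ + 1]
    dmi_dum <- (1 - wf) * (at(f0, m0 + 1) - at(f0, m0)) +
      wf * (at(f0 + 1, m0 + 1) - at(f0 + 1, m0))
    dmi_dum <- dmi_dum / n
    dum_dm <- (nb - 1) / (mrange[2] - mrange[1])
    clamped <- m <= mrange[1] | m >= mrange[2]
    dmi_dum[clamped] <- 0
    out$dm <- -(dmi_dum * dum_dm) / log(2) # cost = -MI_bits
  }
  out
}

# Normalized correlation cost -|r| with optional d(cost)/dm.
ncc_from_samples <- function(f, m, want_dm = FALSE) {
  n <- length(f)
  if (n == 0) stop("empty sample set: mask excludes everything")
  fb <- f - mean(f); mb <- m - mean(m)
  sf <- sqrt(sum(fb^2)); sm <- sqrt(sum(mb^2))
  if (sf == 0 || sm == 0)
    stop("zero intensity variance in the sampled region")
  r <- sum(fb * mb) / (sf * sm)
  out <- list(value = -abs(r), n = n)
  if (want_dm) {
    dr <- fb / (sf * sm) - r * mb / sm^2
    out$dm <- -sign(r) * dr
  }
  out
}

msd_from_samples <- function(f, m, want_dm = FALSE) {
  n <- length(f)
  if (n == 0) stop("empty sample set: mask excludes everything")
  d <- m - f
  out <- list(value = mean(d^2), n = n)
  if (want_dm) out$dm <- 2 * d / n
  out
}

# ---- public metric operations ----------------------------------------------

metric_on_pair <- function(fixed, moving, t, cfg, samples) {
  st <- metric_state(fixed, moving, cfg)
  pick <- sample_points(st, samples, cfg)
  x <- st$fpts[pick, , drop = FALSE]
  f <- st$fvals[pick]
  y <- if (is.null(t)) x else apply_transform(t, x)
  idx <- moving_index(st, y)
  dmax <- st$m_dim - 1
  inside <- idx[, 1] >= 0 & idx[, 2] >= 0 & idx[, 3] >= 0 &
    idx[, 1] <= dmax[1] & idx[, 2] <= dmax[2] & idx[, 3] <= dmax[3]
  if (!any(inside))
    stop("no fixed samples map inside the moving image")
  m <- cpp_interp3(st$m_values, st$m_dim, idx, 1L, cfg$fill)
  mv <- switch(cfg$metric,
    mutual_information = mi_from_samples(f, m, st$frange, st$mrange,
                                         cfg$histogram_bins),
    normalized_correlation = ncc_from_samples(f, m),
    mean_squared_difference = msd_from_samples(f, m))
  list(value = mv$value, n = mv$n, mi = mv$mi,
       inside_fraction = mean(inside))
}

#' Mutual information between a fixed and a transformed moving image
#'
#' Negative mutual information (bits) of the joint intensity histogram of
#' fixed-image sample points and the moving image evaluated at their
#' transformed positions, using linear (partial-volume) binning. Lower values
#' mean better alignment; the returned \code{mi} component is the mutual
#' information itself (>= 0).
#'
#' @param fixed,moving \code{\link{volume_image}}s.
#' @param t transform mapping fixed world points to moving world points
#'   (\code{NULL} = identity).
#' @param cfg a \code{\link{registration_config}}.
#' @param samples number of random fixed samples, or \code{"all"} (default)
#'   for every (masked) fixed voxel.
#' @return list with \code{value} (the cost, = -MI), \code{mi} (bits) and
#'   \code{n} (samples used).
#' @export
mutual_information <- function(fixed, moving, t = NULL,
                               cfg = registration_config(), samples = "all") {
  cfg$metric <- "mutual_information"
  metric_on_pair(fixed, moving, t, cfg, samples)
}

#' Normalized correlation between a fixed and a transformed moving image
#'
#' Cost is minus the absolute Pearson correlation of paired intensities, in
#' [-1, 0]; invariant to affine intensity rescaling of either image.
#'
#' @inheritParams mutual_information
#' @return list with \code{value} and \code{n}.
#' @export
normalized_correlation <- function(fixed, moving, t = NULL,
                                   cfg = registration_config(), samples = "all") {
  cfg$metric <- "normalized_correlation"
  metric_on_pair(fixed, moving, t, cfg, samples)
}

# ---- multiresolution pyramid ------------------------------------------------

gauss_kernel <- function(sd) {
  if (sd <= 0) return(1)
  r <- max(1L, ceiling(3 * sd))
  k <- exp(-(seq(-r, r))^2 / (2 * sd^2))
  k / sum(k)
}

smooth_volume <- function(values, sd) {
  if (sd <= 0) return(values)
  k <- gauss_kernel(sd)
  d <- dim(values)
  v <- as.numeric(values)
  for (axis in 0:2) v <- cpp_smooth_axis(v, d, k, axis)
  array(v, d)
}

#' Build a multiresolution image pyramid
#'
#' Each level smooths the image with the configured Gaussian width and
#' subsamples by the configured factor, keeping grid node 0 so world geometry
#' stays consistent. The finest level is the original image. Levels whose
#' subsampled grid would drop below 4 voxels along any axis are skipped with
#' a warning.
#'
#' @param image a \code{\link{volume_image}}.
#' @param cfg a \code{\link{registration_config}} (uses
#'   \code{pyramid_factors} and \code{pyramid_smooth}).
#' @return list of \code{volume_image}s, coarse to fine.
#' @export
build_pyramid <- function(image, cfg = registration_config()) {
  d <- dim(image$values)
  levels <- list()
  for (i in seq_along(cfg$pyramid_factors)) {
    f <- cfg$pyramid_factors[i]
    nd <- floor((d - 1) / f) + 1
    if (any(nd < 4) && f > 1) {
      warning("image too small for pyramid factor ", f, "; level skipped")
      next
    }
    if (f == 1 && cfg$pyramid_smooth[i] <= 0) {
      levels[[length(levels) + 1L]] <- image
      next
    }
    sm <- smooth_volume(image$values, cfg$pyramid_smooth[i])
    idx <- lapply(d, function(n) seq(1, n, by = f))
    levels[[length(levels) + 1L]] <-
      volume_image(sm[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
                   spacing = image$spacing * f, origin = image$origin,
                   direction = image$direction)
  }
  if (!length(levels)) levels <- list(image)
  levels
}

# nearest-neighbour pyramid for binary masks (no smoothing)
build_mask_pyramid <- function(mask, factors) {
  d <- dim(mask)
  lapply(factors, function(f) {
    nd <- floor((d - 1) / f) + 1
    if (any(nd < 4) && f > 1) return(NULL)
    idx <- lapply(d, function(n) seq(1, n, by = f))
    mask[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  })
}
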