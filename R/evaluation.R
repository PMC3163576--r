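# Quantitative evaluation: landmark RMS distances, reference-plane
# angulation, Jacobian volume changes, and intensity-PDF interquartile
# segmentation.

#' Named landmark points in world coordinates
#'
#' @param points n x 3 matrix of world points (mm) with unique row names
#'   (landmark identifiers), or an unnamed matrix (identifiers L01, L02, ...
#'   are assigned).
#' @param observer,image free-text tags naming the annotating observer and
#'   the parent image.
#' @export
landmark_set <- function(points, observer = "", image = "") {
  points <- as_point_matrix(points)
  if (nrow(points) < 1) stop("a landmark set needs at least one point")
  if (is.null(rownames(points)))
    rownames(points) <- sprintf("L%02d", seq_len(nrow(points)))
  if (anyDuplicated(rownames(points)))
    stop("landmark identifiers must be unique")
  structure(list(points = points, observer = observer, image = image),
            class = "landmark_set")
}

as_landmark_set <- function(x) {
  if (inherits(x, "landmark_set")) x else landmark_set(x)
}

#' Root-mean-squared distance between corresponding landmarks
#'
#' RMS of the Euclidean distances between points with matching identifiers,
#' after optionally mapping the first set through a transform. This is the
#' target registration error measure used throughout the evaluation.
#'
#' @param a,b \code{\link{landmark_set}}s (or plain point matrices) with
#'   matching identifier sets.
#' @param t optional transform applied to \code{a}'s points first.
#' @return RMS distance in mm.
#' @export
landmark_rms <- function(a, b, t = NULL) {
  a <- as_landmark_set(a); b <- as_landmark_set(b)
  ids_a <- rownames(a$points); ids_b <- rownames(b$points)
  miss <- c(setdiff(ids_a, ids_b), setdiff(ids_b, ids_a))
  if (length(miss))
    stop("landmark identifiers do not match: ", paste(miss, collapse = ", "))
  pa <- a$points[ids_a, , drop = FALSE]
  pb <- b$points[ids_a, , drop = FALSE]
  if (!is.null(t)) pa <- apply_transform(t, pa)
  sqrt(mean(rowSums((pa - pb)^2)))
}

#' Interobserver landmark variability
#'
#' RMS distance between the annotations of two observers on the same image
#' (no transform applied).
#' @param obs1,obs2 \code{\link{landmark_set}}s of the two observers.
#' @export
interobserver_rms <- function(obs1, obs2) landmark_rms(obs1, obs2, t = NULL)

#' Relative volume change between two VOI volumes, in percent
#'
#' \code{100 * (V_R - V_O) / V_O}, where \code{V_O} and \code{V_R} are the
#' VOI volumes (mm^3, voxel count times voxel volume) before and after
#' registration.
#'
#' @param v_o,v_r volumes before / after, mm^3 (\code{v_o} must be > 0).
#' @export
volume_change_percent <- function(v_o, v_r) {
  if (any(v_o <= 0)) stop("V_O must be positive")
  100 * (v_r - v_o) / v_o
}

#' Volume of a binary mask in mm^3
#'
#' @param mask logical/0-1 array.
#' @param spacing voxel spacing (mm), or a \code{\link{volume_image}} whose
#'   spacing to use.
#' @export
voi_volume <- function(mask, spacing) {
  if (is_volume_image(spacing)) spacing <- spacing$spacing
  sum(as.logical(mask)) * prod(spacing)
}

#' Global volume change of a registration stage, in percent
#'
#' \code{100 * (det - 1)} of the linear part of the stage's affine (or
#' similarity) transform, taken in the pull-back (fixed to moving) direction.
#' Under the fixed/moving assignments used here this is exactly the physical
#' volume change the processing step applied to the specimen: for ex2in
#' (in vivo fixed, ex vivo moving) it is the fixation shrinkage (about
#' -13 percent); for stack2ex (ex vivo fixed, histology stack moving) it is
#' the sectioning expansion (about +2 percent).
#'
#' @param stage a \code{stage_result} (see \code{\link{stack2ex}}), or a
#'   linear transform.
#' @export
global_volume_change <- function(stage) {
  t <- if (inherits(stage, "stage_result")) {
    if (!is.null(stage$affine)) stage$affine
    else if (!is.null(stage$rigid)) stage$rigid
    else stop("stage has no affine/similarity component")
  } else stage
  100 * (transform_determinant(t) - 1)
}

#' Out-of-plane angulation of a registration stage, in degrees
#'
#' The rotation component of the stage's rigid registration about the two
#' in-plane axes of the reference plane, i.e. the tilt of the plane normal
#' under the recovered rotation. Measures the residual error in reference
#' plane positioning.
#'
#' @param stage a \code{stage_result}, or a rigid/similarity transform.
#' @param plane a \code{\link{reference_plane}} giving the normal in the
#'   registration frame, or a normal vector; default: the slice normal (+z)
#'   of the plane-realigned frames the stages operate in.
#' @export
angulation_report <- function(stage, plane = c(0, 0, 1)) {
  t <- if (inherits(stage, "stage_result")) stage$rigid else stage
  if (is.null(t)) stop("stage has no rigid component")
  n <- if (inherits(plane, "reference_plane")) plane$normal else plane
  out_of_plane_angulation(t, n)
}

# ---- intensity PDFs and interquartile segmentation -------------------------

#' Histogram-based intensity probability density of a VOI
#'
#' Normalized histogram of the image intensities inside a mask, with
#' quartiles computed by linear interpolation of the empirical CDF of the
#' masked intensities (R type-7 quantiles), so that with heavily tied
#' (quantized) data the quartiles land on observed values.
#'
#' @param image a \code{\link{volume_image}} or numeric array.
#' @param mask logical array of the same shape (non-empty).
#' @param bins number of histogram bins (default 64).
#' @return an object of class \code{intensity_pdf}: \code{breaks},
#'   \code{probability} (sums to 1), \code{quartiles} (Q1, Q2, Q3),
#'   \code{range}, \code{n}.
#' @export
estimate_pdf <- function(image, mask = NULL, bins = 64) {
  v <- if (is_volume_image(image)) image$values else image
  x <- if (is.null(mask)) as.numeric(v) else v[as.logical(mask)]
  if (!length(x)) stop("empty mask: no intensities to estimate a pdf from")
  r <- range(x)
  if (r[1] == r[2]) {
    breaks <- r[1] + c(-0.5, 0.5)
    prob <- 1
  } else {
    breaks <- seq(r[1], r[2], length.out = bins + 1)
    prob <- tabulate(pmin(findInterval(x, breaks, all.inside = TRUE), bins),
                     bins)
    prob <- prob / sum(prob)
  }
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
  structure(list(breaks = breaks, probability = prob,
                 quartiles = setNames(q, c("Q1", "Q2", "Q3")),
                 range = r, n = length(x)),
            class = "intensity_pdf")
}

#' @export
print.intensity_pdf <- function(x, ...) {
  cat(sprintf("<intensity_pdf> n = %d, range [%.4g, %.4g], Q1/Q2/Q3 = %.4g/%.4g/%.4g\n",
              x$n, x$range[1], x$range[2],
              x$quartiles[1], x$quartiles[2], x$quartiles[3]))
  invisible(x)
}

#' Segment an image by a VOI's interquartile intensity range
#'
#' Selects voxels whose intensity lies in the closed interval [Q1, Q3] of
#' the given intensity PDF, optionally restricted to a domain mask. This is
#' the automatic segmentation used to test whether a tissue class can be
#' identified from MRI signal intensity alone.
#'
#' @param image a \code{\link{volume_image}} or numeric array.
#' @param pdf an \code{\link{intensity_pdf}} (from \code{\link{estimate_pdf}}).
#' @param domain_mask optional logical array restricting the segmentation.
#' @return logical array of the image's shape.
#' @export
interquartile_segment <- function(image, pdf, domain_mask = NULL) {
  v <- if (is_volume_image(image)) image$values else image
  q1 <- pdf$quartiles[["Q1"]]; q3 <- pdf$quartiles[["Q3"]]
  if (q1 > q3) stop("invalid pdf: Q1 > Q3")
  seg <- v >= q1 & v <= q3
  if (!is.null(domain_mask)) seg <- seg & as.logical(domain_mask)
  seg
}

#' Per-VOI volume changes of a registration stage (Eq.-style report)
#'
#' Warps each VOI mask (nearest-neighbor) from the stage's moving frame onto
#' its fixed grid through the full stage composite and reports
#' \code{\link{volume_change_percent}} between the original and warped
#' volumes.
#'
#' @param stage a \code{stage_result}.
#' @param masks named list of logical arrays on the stage's moving grid.
#' @param moving,fixed \code{\link{volume_image}}s giving the two grids.
#' @return named numeric vector of percent volume changes.
#' @export
voi_volume_changes <- function(stage, masks, moving, fixed) {
  vapply(masks, function(m) {
    mv <- volume_image((m != 0) * 1, spacing = moving$spacing,
                       origin = moving$origin, direction = moving$direction)
    # pull-back: the composite maps fixed points into the moving frame, so
    # resampling onto the fixed grid warps the mask "after registration"
    w <- resample(mv, stage$composite, fixed, scheme = "nearest")
    volume_change_percent(voi_volume(m, moving$spacing),
                          voi_volume(w$values > 0.5, fixed$spacing))
  }, 0)
}
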