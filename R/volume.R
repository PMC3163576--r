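#' 3D scalar image with world geometry
#'
#' A node-centered scalar image on a regular 3D grid. World coordinates (mm)
#' of the 0-based voxel index \code{i} are
#' \code{origin + direction \%*\% (spacing * i)}. Voxel values live at grid
#' nodes.
#'
#' @param values numeric 3D array, dimension \code{(nx, ny, nz)}.
#' @param spacing positive length-3 numeric, mm per axis.
#' @param origin length-3 numeric, mm, world position of voxel (0,0,0).
#' @param direction 3x3 orthonormal matrix with determinant +1 giving the
#'   world direction of each index axis (columns).
#' @return An object of class \code{volume_image}.
#' @export
volume_image <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         direction = diag(3)) {
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  direction <- matrix(as.numeric(direction), 3, 3)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers")
  if (max(abs(crossprod(direction) - diag(3))) > 1e-8 ||
      abs(det(direction) - 1) > 1e-8)
    stop("`direction` must be orthonormal with determinant +1")
  structure(list(values = values, spacing = spacing, origin = origin,
                 direction = direction),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume_image> %d x %d x %d, spacing %s mm, origin %s mm\n",
              d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = " x "),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' @export
dim.volume_image <- function(x) dim(x$values)

is_volume_image <- function(x) inherits(x, "volume_image")

#' Convert world coordinates (mm) to continuous 0-based voxel indices
#'
#' @param image a \code{\link{volume_image}}.
#' @param pts n x 3 matrix (or length-3 vector) of world points in mm.
#' @return n x 3 matrix of continuous 0-based indices.
#' @export
world_to_index <- function(image, pts) {
  pts <- as_point_matrix(pts)
  rel <- sweep(pts, 2, image$origin) %*% image$direction # = t(D) applied rowwise
  sweep(rel, 2, image$spacing, "/")
}

#' Convert 0-based voxel indices to world coordinates (mm)
#'
#' @inheritParams world_to_index
#' @param idx n x 3 matrix (or length-3 vector) of (possibly fractional)
#'   0-based indices.
#' @export
index_to_world <- function(image, idx) {
  idx <- as_point_matrix(idx)
  sweep(sweep(idx, 2, image$spacing, "*") %*% t(image$direction),
        2, image$origin, "+")
}

as_point_matrix <- function(pts, ncol = 3L) {
  if (is.null(dim(pts))) {
    if (length(pts) != ncol) stop("point must have ", ncol, " coordinates")
    pts <- matrix(as.numeric(pts), 1L, ncol)
  } else {
    pts <- as.matrix(pts)
    storage.mode(pts) <- "double"
  }
  if (ncol(pts) != ncol) stop("points must be an n x ", ncol, " matrix")
  pts
}

# world coordinates of every voxel, ordered like the values array
grid_world_points <- function(image) {
  d <- dim(image$values)
  idx <- cbind(rep.int(seq_len(d[1]) - 1, d[2] * d[3]),
               rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3]),
               rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
  index_to_world(image, idx)
}

# world coordinate of the geometric grid center
grid_center <- function(image) {
  as.numeric(index_to_world(image, (dim(image$values) - 1) / 2))
}

#' Interpolate a volume at world points
#'
#' Points outside the node-centered image domain return \code{fill}. The
#' \code{cubic_bspline} scheme prefilters the image so the result interpolates
#' the stored node values exactly.
#'
#' @param image a \code{\link{volume_image}}.
#' @param points n x 3 matrix (or length-3 vector) of world points in mm.
#' @param scheme interpolation scheme.
#' @param fill value returned outside the image domain.
#' @return numeric vector of interpolated intensities.
#' @export
interpolate <- function(image, points,
                        scheme = c("linear", "nearest", "cubic_bspline"),
                        fill = 0) {
  scheme <- match.arg(scheme)
  pts <- as_point_matrix(points)
  if (any(!is.finite(pts)))
    stop("geometry error: non-finite point coordinates")
  idx <- world_to_index(image, pts)
  v <- image$values
  if (scheme == "cubic_bspline")
    v <- array(cpp_bspline_prefilter(as.numeric(v), dim(v)), dim(v))
  code <- c(nearest = 0L, linear = 1L, cubic_bspline = 3L)[[scheme]]
  cpp_interp3(as.numeric(v), dim(v), idx, code, fill)
}

#' Resample a volume through a transform onto a reference grid
#'
#' Pull-back convention: \code{transform} maps points of the reference grid
#' (fixed world frame) into the moving image's world frame. Each output voxel
#' is \code{interpolate(moving, transform(world(index)))}.
#'
#' @param moving the \code{\link{volume_image}} to resample.
#' @param transform a transform (see \code{\link{rigid3}} and friends), or
#'   \code{NULL} for identity.
#' @param reference a \code{volume_image} providing the output grid geometry.
#' @inheritParams interpolate
#' @return a \code{volume_image} on the reference grid.
#' @export
resample <- function(moving, transform = NULL, reference = moving,
                     scheme = c("linear", "nearest", "cubic_bspline"),
                     fill = 0) {
  scheme <- match.arg(scheme)
  pts <- grid_world_points(reference)
  if (!is.null(transform)) {
    check_invertible(transform)
    pts <- apply_transform(transform, pts)
  }
  vals <- interpolate(moving, pts, scheme = scheme, fill = fill)
  volume_image(array(vals, dim(reference$values)),
               spacing = reference$spacing, origin = reference$origin,
               direction = reference$direction)
}

check_invertible <- function(t) {
  if (inherits(t, "affine3") && abs(det(t$matrix)) < 1e-12)
    stop("singular transform: affine matrix is not invertible")
  if (inherits(t, "composite3"))
    lapply(t$components, check_invertible)
  invisible(TRUE)
}

#' Reference cutting plane
#'
#' The physical plane cut through the fixed tumor along its longest axis,
#' perpendicular to the subcutaneous side; shared anchor of the in vivo,
#' ex vivo and histology frames.
#'
#' @param normal unit normal of the plane (in vivo world frame).
#' @param point a point on the plane, mm.
#' @param in_plane_axes 3 x 2 matrix whose columns are orthonormal in-plane
#'   axes; derived from the normal when omitted.
#' @export
reference_plane <- function(normal, point, in_plane_axes = NULL) {
  normal <- as.numeric(normal)
  normal <- normal / sqrt(sum(normal^2))
  point <- as.numeric(point)
  if (is.null(in_plane_axes)) {
    seed <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- seed - sum(seed * normal) * normal
    u <- u / sqrt(sum(u^2))
    v <- c(normal[2] * u[3] - normal[3] * u[2],
           normal[3] * u[1] - normal[1] * u[3],
           normal[1] * u[2] - normal[2] * u[1])
    in_plane_axes <- cbind(u, v)
  }
  in_plane_axes <- matrix(as.numeric(in_plane_axes), 3, 2)
  g <- crossprod(cbind(in_plane_axes, normal))
  if (max(abs(g - diag(3))) > 1e-6)
    stop("plane axes and normal must be mutually orthonormal")
  structure(list(normal = normal, point = point,
                 in_plane_axes = in_plane_axes),
            class = "reference_plane")
}

#' Realign a volume so the reference plane becomes the first slice
#'
#' Resamples \code{invivo} onto a grid whose slice 0 lies in the reference
#' plane with slice normal equal to the plane normal, as preparation for
#' registration against the ex vivo MRI (which starts at the same physical
#' plane).
#'
#' @param invivo a \code{\link{volume_image}}.
#' @param plane a \code{\link{reference_plane}}; must intersect the image.
#' @param out_spacing output spacing, mm (default: input spacing).
#' @param out_shape output grid shape (default: input shape).
#'
#' The default interpolation is the interpolating cubic B-spline: the
#' realigned volume becomes the fixed image of the ex2in registration, and
#' the resolution loss of linear resampling on an oblique grid is not
#' shared by the native moving image, which measurably biases the
#' recovered scale (fixation volume change).
#' @inheritParams interpolate
#' @return a \code{volume_image}; attribute \code{"grid_transform"} holds the
#'   affine mapping realigned world coordinates to the original world frame
#'   (here the realigned frame has the plane point at the in-plane center of
#'   slice 0, so the mapping is the rigid grid pose itself).
#' @export
realign_to_reference_plane <- function(invivo, plane, out_spacing = NULL,
                                       out_shape = NULL,
                                       scheme = c("cubic_bspline", "linear",
                                                  "nearest"),
                                       fill = 0) {
  scheme <- match.arg(scheme)
  if (is.null(out_spacing)) out_spacing <- invivo$spacing
  if (is.null(out_shape)) out_shape <- dim(invivo$values)
  idx <- world_to_index(invivo, plane$point)
  d <- dim(invivo$values)
  if (any(idx < -0.5) || any(idx > d - 0.5))
    stop("reference plane lies outside the image domain")
  dir_out <- cbind(plane$in_plane_axes, plane$normal)
  if (det(dir_out) < 0) { # keep a right-handed frame
    dir_out[, 2] <- -dir_out[, 2]
  }
  origin_out <- plane$point -
    dir_out[, 1] * (out_shape[1] - 1) / 2 * out_spacing[1] -
    dir_out[, 2] * (out_shape[2] - 1) / 2 * out_spacing[2]
  ref <- volume_image(array(0, out_shape), spacing = out_spacing,
                      origin = origin_out, direction = dir_out)
  out <- resample(invivo, transform = NULL, reference = ref,
                  scheme = scheme, fill = fill)
  # rigid map: realigned world frame == original world frame (identity); the
  # useful bookkeeping is the grid pose itself
  attr(out, "grid_transform") <- affine3(matrix = dir_out,
                                         translation = origin_out,
                                         center = c(0, 0, 0))
  out
}

#' Dice overlap of two binary masks
#'
#' @param a,b logical/0-1 arrays of identical shape.
#' @return Dice coefficient in [0, 1].
#' @export
dice_overlap <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}
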