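#' Transform models
#'
#' Geometric transforms mapping world points (mm) to world points, used with
#' the pull-back convention: a registration transform maps fixed-image world
#' points into the moving image's world frame.
#'
#' Euler angles use the intrinsic x, then y, then z convention,
#' \code{R = Rx(a) Ry(b) Rz(c)}; angles are in radians.
#'
#' @param angles length-3 Euler angles (radians).
#' @param translation length-3 translation (mm).
#' @param center length-3 center of rotation (mm).
#' @return a transform object inheriting from \code{hm_transform}.
#' @name transforms
NULL

#' @rdname transforms
#' @export
rigid3 <- function(angles = c(0, 0, 0), translation = c(0, 0, 0),
                   center = c(0, 0, 0)) {
  structure(list(angles = as.numeric(angles),
                 translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = c("rigid3", "hm_transform"))
}

#' @rdname transforms
#' @param scale positive isotropic scale factor.
#' @export
similarity3 <- function(angles = c(0, 0, 0), translation = c(0, 0, 0),
                        center = c(0, 0, 0), scale = 1) {
  stopifnot(is.finite(scale), scale > 0)
  structure(list(angles = as.numeric(angles),
                 translation = as.numeric(translation),
                 center = as.numeric(center), scale = as.numeric(scale)),
            class = c("similarity3", "hm_transform"))
}

#' @rdname transforms
#' @param matrix 3x3 non-singular linear part.
#' @export
affine3 <- function(matrix = diag(3), translation = c(0, 0, 0),
                    center = c(0, 0, 0)) {
  matrix <- base::matrix(as.numeric(matrix), 3, 3)
  if (abs(det(matrix)) < 1e-15) stop("affine matrix must be non-singular")
  structure(list(matrix = matrix, translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = c("affine3", "hm_transform"))
}

#' Free-form cubic B-spline transform
#'
#' Displacement field \code{D(p)} as a tensor-product cubic B-spline of
#' control-point coefficients; the transform maps \code{p} to \code{p + D(p)}.
#' Outside the control-grid support the displacement is zero (identity).
#'
#' @param grid_origin world position (mm) of control point (0,0,0).
#' @param grid_spacing control-point spacing per axis (mm).
#' @param coef 4D array \code{(ncx, ncy, ncz, 3)} of displacements (mm).
#' @export
bspline3 <- function(grid_origin, grid_spacing, coef) {
  stopifnot(length(dim(coef)) == 4L, dim(coef)[4] == 3L)
  structure(list(grid_origin = as.numeric(grid_origin),
                 grid_spacing = as.numeric(grid_spacing),
                 coef = coef),
            class = c("bspline3", "hm_transform"))
}

#' @rdname transforms
#' @param ... component transforms, applied in the order given (point goes
#'   through the first component first).
#' @export
composite_transform <- function(...) {
  comps <- list(...)
  if (length(comps) == 1L && is.list(comps[[1]]) &&
      !inherits(comps[[1]], "hm_transform"))
    comps <- comps[[1]]
  flat <- list()
  for (tr in comps) {
    stopifnot(inherits(tr, "hm_transform"))
    if (inherits(tr, "composite3")) flat <- c(flat, tr$components)
    else flat <- c(flat, list(tr))
  }
  structure(list(components = flat),
            class = c("composite3", "hm_transform"))
}

#' 2D rigid transform (section stacking)
#'
#' @param angle rotation (radians).
#' @param translation length-2 translation (mm).
#' @param center length-2 rotation center (mm).
#' @export
rigid2 <- function(angle = 0, translation = c(0, 0), center = c(0, 0)) {
  structure(list(angle = as.numeric(angle),
                 translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = c("rigid2", "hm_transform"))
}

# ---- rotation helpers -------------------------------------------------------

rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
rot_y <- function(b) matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
rot_z <- function(c_) matrix(c(cos(c_), sin(c_), 0, -sin(c_), cos(c_), 0, 0, 0, 1), 3, 3)

#' Rotation matrix from intrinsic x-y-z Euler angles
#' @param angles length-3 numeric, radians.
#' @export
euler_to_matrix <- function(angles) {
  rot_x(angles[1]) %*% rot_y(angles[2]) %*% rot_z(angles[3])
}

#' Euler angles (intrinsic x-y-z) from a rotation matrix
#'
#' At gimbal lock (second angle +-90 degrees) the third angle is set to 0.
#' @param R 3x3 rotation matrix.
#' @return length-3 numeric, radians.
#' @export
matrix_to_euler <- function(R) {
  sb <- max(-1, min(1, R[1, 3]))
  b <- asin(sb)
  if (abs(sb) < 1 - 1e-10) {
    a <- atan2(-R[2, 3], R[3, 3])
    c_ <- atan2(-R[1, 2], R[1, 1])
  } else { # gimbal lock: set third angle to 0
    a <- atan2(R[2, 1], R[2, 2])
    c_ <- 0
  }
  c(a, b, c_)
}

# linear part of a transform with one
linear_part <- function(t) {
  if (inherits(t, "rigid3")) euler_to_matrix(t$angles)
  else if (inherits(t, "similarity3")) t$scale * euler_to_matrix(t$angles)
  else if (inherits(t, "affine3")) t$matrix
  else stop("transform has no linear part")
}

# ---- point application ------------------------------------------------------

#' Apply a transform to world points
#'
#' @param t a transform.
#' @param pts n x 3 matrix (n x 2 for \code{rigid2}) or a single point.
#' @return matrix of mapped points, same shape as the input matrix.
#' @export
apply_transform <- function(t, pts) UseMethod("apply_transform")

apply_linear <- function(M, center, translation, pts) {
  rel <- sweep(pts, 2, center)
  sweep(rel %*% t(M), 2, center + translation, "+")
}

#' @export
apply_transform.rigid3 <- function(t, pts) {
  pts <- as_point_matrix(pts)
  stopifnot(all(is.finite(pts)))
  apply_linear(euler_to_matrix(t$angles), t$center, t$translation, pts)
}

#' @export
apply_transform.similarity3 <- function(t, pts) {
  pts <- as_point_matrix(pts)
  stopifnot(all(is.finite(pts)))
  apply_linear(t$scale * euler_to_matrix(t$angles), t$center, t$translation, pts)
}

#' @export
apply_transform.affine3 <- function(t, pts) {
  pts <- as_point_matrix(pts)
  stopifnot(all(is.finite(pts)))
  apply_linear(t$matrix, t$center, t$translation, pts)
}

#' @export
apply_transform.bspline3 <- function(t, pts) {
  pts <- as_point_matrix(pts)
  stopifnot(all(is.finite(pts)))
  pts + bspline_displacement(t, pts)
}

#' @export
apply_transform.composite3 <- function(t, pts) {
  pts <- as_point_matrix(pts)
  for (comp in t$components) pts <- apply_transform(comp, pts)
  pts
}

#' @export
apply_transform.rigid2 <- function(t, pts) {
  pts <- as_point_matrix(pts, 2L)
  stopifnot(all(is.finite(pts)))
  R <- matrix(c(cos(t$angle), sin(t$angle), -sin(t$angle), cos(t$angle)), 2, 2)
  rel <- sweep(pts, 2, t$center)
  sweep(rel %*% t(R), 2, t$center + t$translation, "+")
}

#' Displacement of a B-spline transform at world points
#'
#' Zero outside the control-grid support.
#' @param t a \code{\link{bspline3}} transform.
#' @param pts n x 3 matrix of world points (mm).
#' @return n x 3 matrix of displacements (mm).
#' @export
bspline_displacement <- function(t, pts) {
  pts <- as_point_matrix(pts)
  cd <- dim(t$coef)[1:3]
  cpp_bspline_disp(as.numeric(t$coef), cd, t$grid_origin, t$grid_spacing, pts)
}

# ---- composition ------------------------------------------------------------

#' Concatenate two transforms
#'
#' \code{compose_transforms(a, b)} applies \code{a} first, then \code{b}:
#' \code{apply_transform(compose_transforms(a, b), p) ==
#' apply_transform(b, apply_transform(a, p))}. With \code{collapse = TRUE}
#' chains of purely linear transforms are merged into a single
#' \code{\link{affine3}} with identical action.
#'
#' @param a,b transforms; \code{a} is applied first.
#' @param collapse merge adjacent linear components into one affine.
#' @export
compose_transforms <- function(a, b, collapse = FALSE) {
  out <- composite_transform(a, b)
  if (collapse) out <- collapse_linear(out)
  out
}

is_linear3 <- function(t)
  inherits(t, "rigid3") || inherits(t, "similarity3") || inherits(t, "affine3")

# convert any linear transform to (M, d) with y = M p + d
linear_md <- function(t) {
  M <- linear_part(t)
  d <- t$center + t$translation - M %*% t$center
  list(M = M, d = as.numeric(d))
}

#' Collapse chains of linear components of a composite into single affines
#' @param t a transform.
#' @return a transform with identical action; a purely linear composite
#'   becomes one \code{\link{affine3}}.
#' @export
collapse_linear <- function(t) {
  if (!inherits(t, "composite3")) return(t)
  out <- list()
  pend <- NULL # pending collapsed linear (M, d), y = M p + d
  flush <- function() {
    if (!is.null(pend))
      out[[length(out) + 1L]] <<- affine3(matrix = pend$M,
                                          translation = pend$d,
                                          center = c(0, 0, 0))
    pend <<- NULL
  }
  for (comp in t$components) {
    if (is_linear3(comp)) {
      md <- linear_md(comp)
      if (is.null(pend)) pend <- md
      else pend <- list(M = md$M %*% pend$M,
                        d = as.numeric(md$M %*% pend$d + md$d))
    } else {
      flush()
      out[[length(out) + 1L]] <- comp
    }
  }
  flush()
  if (length(out) == 1L) out[[1L]] else composite_transform(out)
}

# ---- inversion --------------------------------------------------------------

#' Invert a transform
#'
#' Closed form for linear transforms; fixed-point iteration for B-spline
#' displacements (accurate for the smooth, moderate deformations used here);
#' reversed component inverses for composites.
#' @param t a transform.
#' @return a function mapping an n x 3 point matrix to the preimage points.
#' @export
invert_transform <- function(t) {
  if (is_linear3(t)) {
    md <- linear_md(t)
    Minv <- solve(md$M)
    d <- as.numeric(Minv %*% md$d)
    function(pts) sweep(as_point_matrix(pts) %*% t(Minv), 2, d)
  } else if (inherits(t, "bspline3")) {
    function(pts) {
      pts <- as_point_matrix(pts)
      y <- pts
      for (i in seq_len(25)) {
        y_new <- pts - bspline_displacement(t, y)
        if (max(abs(y_new - y)) < 1e-10) { y <- y_new; break }
        y <- y_new
      }
      y
    }
  } else if (inherits(t, "composite3")) {
    invs <- lapply(rev(t$components), invert_transform)
    function(pts) {
      pts <- as_point_matrix(pts)
      for (f in invs) pts <- f(pts)
      pts
    }
  } else if (inherits(t, "rigid2")) {
    function(pts) {
      pts <- as_point_matrix(pts, 2L)
      R <- matrix(c(cos(t$angle), sin(t$angle), -sin(t$angle), cos(t$angle)), 2, 2)
      rel <- sweep(pts, 2, t$center + t$translation)
      sweep(rel %*% R, 2, t$center, "+") # %*% R == %*% t(Rinv)
    }
  } else stop("cannot invert transform of class ", class(t)[1])
}

# ---- derived quantities -----------------------------------------------------

#' Euler angles of a rigid transform, in degrees
#'
#' Reported in the intrinsic x, y, z order. At gimbal lock the third angle is
#' set to 0 by convention.
#' @param t a \code{\link{rigid3}} or \code{\link{similarity3}} transform.
#' @return length-3 numeric, degrees.
#' @export
rotation_angles_deg <- function(t) {
  stopifnot(inherits(t, "rigid3") || inherits(t, "similarity3"))
  matrix_to_euler(euler_to_matrix(t$angles)) * 180 / pi
}

#' Determinant of the linear part of a transform
#'
#' For a similarity transform this equals \code{scale^3}; it is the local
#' volume scaling factor of the transform (Jacobian determinant for linear
#' transforms).
#' @param t a linear (\code{rigid3}, \code{similarity3}, \code{affine3})
#'   transform, or a composite of such.
#' @export
transform_determinant <- function(t) {
  if (inherits(t, "composite3")) {
    t <- collapse_linear(t)
    if (!is_linear3(t)) stop("composite contains non-linear components")
  }
  det(linear_part(t))
}

#' Out-of-plane angulation of a rigid rotation, in degrees
#'
#' The angle between the reference-plane normal and its image under the
#' rotation: the magnitude of the rotation component about the two in-plane
#' axes. Exactly zero for a pure in-plane rotation.
#' @param t a \code{\link{rigid3}} or \code{\link{similarity3}} transform.
#' @param normal plane normal in the frame the transform acts in (default:
#'   the slice normal of a realigned/stack frame, +z).
#' @export
out_of_plane_angulation <- function(t, normal = c(0, 0, 1)) {
  R <- euler_to_matrix(t$angles)
  n <- normal / sqrt(sum(normal^2))
  acos(max(-1, min(1, sum(n * (R %*% n))))) * 180 / pi
}
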