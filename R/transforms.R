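#' Spatial transforms between image spaces
#'
#' All transforms map world coordinates (micrometres) of a *reference* space
#' to world coordinates of a *floating* space, the pull-back convention used
#' for resampling: `resample(flo, t, grid)` fills each grid voxel `x` with
#' `flo(t(x))`.  A registration of `flo` onto `ref` therefore returns the
#' transform that, applied to `ref` coordinates, lands on the matching `flo`
#' coordinates.
#'
#' @name transforms
NULL

#' 2D affine transform (coronal plane)
#'
#' @param matrix 2x2 linear part.
#' @param translation length-2 translation in micrometres.
#' @return an object of class \code{c("affine2d", "h3d_transform")}.
#' @export
affine2d <- function(matrix = diag(2), translation = c(0, 0)) {
  matrix <- base::matrix(as.numeric(matrix), 2, 2)
  if (abs(det(matrix)) <= 1e-8)
    .h3d_stop("h3d_singular_transform", "affine2d linear part is singular")
  structure(list(matrix = matrix, translation = as.numeric(translation)),
            class = c("affine2d", "h3d_transform"))
}

#' 3D rigid transform (Euler angles)
#'
#' Rotation follows the intrinsic z-y-x Euler convention in degrees: first a
#' rotation about z, then about the rotated y, then about the rotated x, i.e.
#' \code{R = Rz(a) Ry(b) Rx(c)}.
#'
#' @param rotation length-3 Euler angles (degrees), order (z, y, x).
#' @param translation length-3 translation in micrometres.
#' @param center optional length-3 rotation centre in micrometres (default
#'   origin); the transform is \code{x -> R (x - center) + center + t}.
#' @export
rigid3d <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                    center = c(0, 0, 0)) {
  structure(list(rotation = as.numeric(rotation),
                 translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = c("rigid3d", "h3d_transform"))
}

#' 3D affine transform
#'
#' @param matrix 3x3 linear part (must be invertible).
#' @param translation length-3 translation in micrometres.
#' @export
affine3d <- function(matrix = diag(3), translation = c(0, 0, 0)) {
  matrix <- base::matrix(as.numeric(matrix), 3, 3)
  if (abs(det(matrix)) <= 1e-8)
    .h3d_stop("h3d_singular_transform", "affine3d linear part is singular")
  structure(list(matrix = matrix, translation = as.numeric(translation)),
            class = c("affine3d", "h3d_transform"))
}

#' Free-form deformation on a cubic B-spline control lattice
#'
#' The lattice spans the reference volume: \code{g} control points per axis
#' give \code{g - 3} spline cells over \code{[0, extent]}.  The transform is
#' \code{x -> bulk(x) + disp(x)} where \code{disp} is the B-spline
#' interpolation of the control-point displacement vectors (micrometres,
#' expressed in floating-space axes) and \code{bulk} an affine applied before
#' the elastic part.  A zero control grid reduces the transform to its bulk
#' affine.
#'
#' @param control_grid numeric array \code{(gx, gy, gz, 3)} of displacement
#'   vectors in micrometres; default a zero 10 x 10 x 10 grid.
#' @param extent length-3 physical extent of the reference volume (um).
#' @param bulk an [affine3d()] (or [rigid3d()], converted) applied before the
#'   elastic displacement.
#' @export
ffd3d <- function(control_grid = array(0, c(10, 10, 10, 3)), extent,
                  bulk = affine3d()) {
  control_grid <- as.array(control_grid)
  d <- dim(control_grid)
  if (length(d) != 4L || d[4] != 3L || any(d[1:3] < 4L))
    .h3d_stop("h3d_value_error",
              "control_grid must be (gx, gy, gz, 3) with at least 4 points per axis")
  if (inherits(bulk, "rigid3d")) bulk <- as_affine3d(bulk)
  stopifnot(inherits(bulk, "affine3d"))
  extent <- as.numeric(extent)
  stopifnot(length(extent) == 3L, all(extent > 0))
  structure(list(control_grid = control_grid, extent = extent, bulk = bulk),
            class = c("ffd3d", "h3d_transform"))
}

#' @export
print.h3d_transform <- function(x, ...) {
  cat(sprintf("<%s transform>\n", class(x)[1]))
  str(unclass(x), max.level = 1, give.attr = FALSE)
  invisible(x)
}

.euler_matrix <- function(deg) {
  r <- deg * pi / 180
  cz <- cos(r[1]); sz <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cx <- cos(r[3]); sx <- sin(r[3])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Convert a rigid transform to its affine form
#' @param t a [rigid3d()].
#' @export
as_affine3d <- function(t) {
  if (inherits(t, "affine3d")) return(t)
  stopifnot(inherits(t, "rigid3d"))
  R <- .euler_matrix(t$rotation)
  # x -> R (x - c) + c + t  ==  R x + (c + t - R c)
  affine3d(R, t$center + t$translation - as.numeric(R %*% t$center))
}

#' Apply a transform to points
#'
#' @param t a transform.
#' @param pts \code{n x 2} (affine2d) or \code{n x 3} matrix of world
#'   coordinates in micrometres.
#' @return matrix of mapped coordinates, same shape.
#' @export
apply_transform <- function(t, pts) UseMethod("apply_transform")

#' @export
apply_transform.affine2d <- function(t, pts) {
  pts <- base::matrix(pts, ncol = 2)
  sweep(pts %*% t(t$matrix), 2, t$translation, "+")
}

#' @export
apply_transform.affine3d <- function(t, pts) {
  pts <- base::matrix(pts, ncol = 3)
  sweep(pts %*% t(t$matrix), 2, t$translation, "+")
}

#' @export
apply_transform.rigid3d <- function(t, pts) apply_transform(as_affine3d(t), pts)

#' @export
apply_transform.ffd3d <- function(t, pts) {
  pts <- base::matrix(pts, ncol = 3)
  disp <- .cpp_bspline_disp(as.numeric(t$control_grid),
                            dim(t$control_grid)[1:3], pts, t$extent)
  apply_transform(t$bulk, pts) + disp
}

#' Compose two transforms
#'
#' Returns the transform \code{x -> a(b(x))} (function composition `a o b`).
#' With the pull-back convention this means
#' \code{resample(resample(v, a), b) == resample(v, compose_transforms(a, b))}.
#' Affine/rigid pairs compose in closed form; any composition involving an
#' elastic transform is returned as a lazily evaluated composite.
#'
#' @param a,b transforms.
#' @export
compose_transforms <- function(a, b) {
  a2 <- if (inherits(a, "rigid3d")) as_affine3d(a) else a
  b2 <- if (inherits(b, "rigid3d")) as_affine3d(b) else b
  if (inherits(a2, "affine2d") && inherits(b2, "affine2d"))
    return(affine2d(a2$matrix %*% b2$matrix,
                    as.numeric(a2$matrix %*% b2$translation) + a2$translation))
  if (inherits(a2, "affine3d") && inherits(b2, "affine3d"))
    return(affine3d(a2$matrix %*% b2$matrix,
                    as.numeric(a2$matrix %*% b2$translation) + a2$translation))
  if (inherits(a2, "ffd3d") && inherits(b2, "affine3d")) {
    # a(b(x)) = bulk_a(b(x)) + disp_a(b(x)): exact only when disp is
    # re-evaluated at b(x); fall back to a generic composite
  }
  structure(list(outer = a, inner = b),
            class = c("composite_transform", "h3d_transform"))
}

#' @export
apply_transform.composite_transform <- function(t, pts)
  apply_transform(t$outer, apply_transform(t$inner, pts))

#' Invert a transform
#'
#' Affine and rigid transforms invert in closed form.  Elastic transforms are
#' only approximately invertible and are refused here.
#'
#' @param t a transform.
#' @export
invert_transform <- function(t) UseMethod("invert_transform")

#' @export
invert_transform.affine2d <- function(t) {
  Mi <- solve(t$matrix)
  affine2d(Mi, -as.numeric(Mi %*% t$translation))
}

#' @export
invert_transform.affine3d <- function(t) {
  Mi <- solve(t$matrix)
  affine3d(Mi, -as.numeric(Mi %*% t$translation))
}

#' @export
invert_transform.rigid3d <- function(t) invert_transform(as_affine3d(t))

#' @export
invert_transform.ffd3d <- function(t)
  .h3d_stop("h3d_value_error",
            "free-form deformations are only approximately invertible; none is computed")

#' Serialize a transform to JSON
#'
#' Parameters are stored with a type tag and the world-unit convention
#' (micrometres); FFD control grids are embedded as nested arrays.
#'
#' @param t a transform.
#' @param path file path; \code{NULL} returns the JSON string.
#' @export
write_transform <- function(t, path = NULL) {
  rec <- switch(class(t)[1],
    affine2d = list(type = "affine2d", matrix = t$matrix, translation = t$translation),
    affine3d = list(type = "affine3d", matrix = t$matrix, translation = t$translation),
    rigid3d = list(type = "rigid3d", rotation = t$rotation,
                   translation = t$translation, center = t$center),
    ffd3d = list(type = "ffd3d", grid_shape = dim(t$control_grid),
                 control_grid = as.numeric(t$control_grid), extent = t$extent,
                 bulk = list(matrix = t$bulk$matrix, translation = t$bulk$translation)),
    .h3d_stop("h3d_value_error", "cannot serialize transform of class %s", class(t)[1]))
  rec$units <- "um"
  rec$euler_convention <- if (rec$type == "rigid3d") "intrinsic z-y-x, degrees" else NULL
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' Read a transform from JSON
#' @param path file path or JSON string written by [write_transform()].
#' @export
read_transform <- function(path) {
  rec <- jsonlite::fromJSON(path)
  switch(rec$type,
    affine2d = affine2d(rec$matrix, rec$translation),
    affine3d = affine3d(rec$matrix, rec$translation),
    rigid3d = rigid3d(rec$rotation, rec$translation, rec$center),
    ffd3d = ffd3d(array(rec$control_grid, rec$grid_shape), rec$extent,
                  affine3d(rec$bulk$matrix, rec$bulk$translation)),
    .h3d_stop("h3d_value_error", "unknown transform type %s", rec$type))
}
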