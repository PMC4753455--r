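#' Voxel volume with physical voxel sizes
#'
#' The universal carrier for block-face, histology, label, mask and heat-map
#' data: a rank-3 grid of scalar samples (or rank-4 with a trailing colour
#' axis of size 3) plus physical voxel sizes in micrometres.  Axes follow the
#' neuroanatomical convention used throughout the package: x = medio-lateral,
#' y = dorso-ventral, z = rostro-caudal, so a coronal section is an x-y plane.
#' Voxel centres sit at \code{(i + 0.5) * d} in world micrometres (0-based
#' voxel indices, world origin at the grid corner).
#'
#' @param data numeric array, rank 3, or rank 4 with \code{dim[4] == 3} for
#'   RGB histology.
#' @param voxel_size numeric length-3, voxel edge lengths \code{(dx, dy, dz)}
#'   in micrometres; all strictly positive.
#' @param modality one of \code{"blockface"}, \code{"histology"},
#'   \code{"label"}, \code{"heatmap"}, \code{"mask"}, \code{"mri"}.
#' @param valid_planes logical vector, one flag per z plane; planes flagged
#'   \code{FALSE} (e.g. missing sections that were zero-filled) are excluded
#'   from all quantifications.  Defaults to all \code{TRUE}.
#' @return an object of class \code{"volume"}.
#' @examples
#' v <- volume(array(0, c(4, 4, 2)), c(25, 25, 125), "blockface")
#' dim(v)
#' @export
volume <- function(data, voxel_size, modality = c("blockface", "histology",
                   "label", "heatmap", "mask", "mri"),
                   valid_planes = NULL) {
  modality <- match.arg(modality)
  data <- as.array(data)
  nd <- length(dim(data))
  if (!(nd == 3L || (nd == 4L && dim(data)[4] == 3L)))
    .h3d_stop("h3d_shape_error",
              "volume data must be rank 3 or rank 4 with a trailing colour axis of size 3, got rank %d", nd)
  if (any(dim(data) < 1L))
    .h3d_stop("h3d_value_error", "all volume dimensions must be >= 1")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    .h3d_stop("h3d_value_error", "voxel_size must be 3 strictly positive values (um)")
  nz <- dim(data)[3]
  if (is.null(valid_planes)) valid_planes <- rep(TRUE, nz)
  if (length(valid_planes) != nz)
    .h3d_stop("h3d_value_error", "valid_planes must have one flag per z plane")
  if (modality == "label") {
    if (any(data < 0) || any(data != round(data)))
      .h3d_stop("h3d_value_error", "label volumes must contain non-negative integers")
    storage.mode(data) <- "integer"
  }
  if (modality == "mask" && !all(data %in% c(0, 1)))
    .h3d_stop("h3d_value_error", "mask volumes must contain only 0 and 1")
  structure(list(data = data,
                 voxel_size = setNames(voxel_size, c("dx", "dy", "dz")),
                 modality = modality,
                 valid_planes = as.logical(valid_planes)),
            class = "volume")
}

#' @export
dim.volume <- function(x) dim(x$data)

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume> %s  %s voxels  @ %s um%s\n", x$modality,
              paste(d[1:3], collapse = " x "),
              paste(signif(x$voxel_size, 6), collapse = " x "),
              if (length(d) == 4L) "  (RGB)" else ""))
  if (!all(x$valid_planes))
    cat(sprintf("  %d/%d z planes flagged invalid\n",
                sum(!x$valid_planes), length(x$valid_planes)))
  invisible(x)
}

#' @export
is_volume <- function(x) inherits(x, "volume")

#' Physical extent of a volume in micrometres
#'
#' @param vol a [volume()].
#' @return numeric length-3, \code{dim * voxel_size} per axis.
#' @export
volume_extent <- function(vol) {
  stopifnot(is_volume(vol))
  unname(dim(vol$data)[1:3] * vol$voxel_size)
}

#' World coordinates of every voxel centre
#'
#' @param vol a [volume()] (only dims and voxel sizes are used).
#' @return an \code{n x 3} matrix of world coordinates in micrometres, in
#'   column-major voxel order (x fastest).
#' @export
voxel_centers <- function(vol) {
  d <- dim(vol$data)[1:3]
  vs <- vol$voxel_size
  xs <- (seq_len(d[1]) - 0.5) * vs[1]
  ys <- (seq_len(d[2]) - 0.5) * vs[2]
  zs <- (seq_len(d[3]) - 0.5) * vs[3]
  cbind(rep(xs, times = d[2] * d[3]),
        rep(rep(ys, each = d[1]), times = d[3]),
        rep(zs, each = d[1] * d[2]))
}

#' Total tissue volume of a mask in cubic millimetres
#'
#' @param mask a mask [volume()].
#' @return scalar, voxel count times voxel volume, in mm^3.
#' @export
mask_volume_mm3 <- function(mask) {
  stopifnot(is_volume(mask), mask$modality == "mask")
  sum(mask$data) * prod(mask$voxel_size) * 1e-9
}
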