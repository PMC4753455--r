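#' Ordered series of 2D sections
#'
#' Holds the stained (or photographed) coronal sections of one marker, in
#' rostro-caudal order, together with the sampling design: every
#' \code{interleave}-th physical section of thickness
#' \code{section_thickness} is retained, so consecutive kept sections are
#' \code{section_thickness * interleave} micrometres apart.  \code{z_indices}
#' give, for each image, the index of its corresponding block-face plane
#' (0-based); gaps mark lost or damaged sections.
#'
#' @param images list of images: matrices (grayscale) or \code{(nx, ny, 3)}
#'   arrays (RGB), all the same pixel dimensions.
#' @param z_indices integer vector, strictly increasing, same length as
#'   \code{images}.
#' @param in_plane_resolution um per pixel in x and y.
#' @param section_thickness physical section thickness in um.
#' @param interleave sampling period among physical sections (>= 1).
#' @export
section_series <- function(images, z_indices = seq_along(images) - 1L,
                           in_plane_resolution, section_thickness,
                           interleave = 1L) {
  if (length(images) == 0L)
    .h3d_stop("h3d_value_error", "section series is empty")
  z_indices <- as.integer(z_indices)
  if (length(z_indices) != length(images))
    .h3d_stop("h3d_value_error", "one z index per image is required")
  if (any(diff(z_indices) <= 0L))
    .h3d_stop("h3d_value_error", "z_indices must be strictly increasing")
  if (interleave < 1L)
    .h3d_stop("h3d_value_error", "interleave must be >= 1")
  structure(list(images = images, z_indices = z_indices,
                 in_plane_resolution = as.numeric(in_plane_resolution),
                 section_thickness = as.numeric(section_thickness),
                 interleave = as.integer(interleave)),
            class = "section_series")
}

#' @export
print.section_series <- function(x, ...) {
  cat(sprintf("<section_series> %d images @ %g um/px, %g um sections, 1/%d sampling\n",
              length(x$images), x$in_plane_resolution, x$section_thickness,
              x$interleave))
  invisible(x)
}

#' Stack a section series into a volume
#'
#' Plane \code{z} of the output holds the image with that z index; block-face
#' planes without an image (gaps in \code{z_indices}) are zero-filled and
#' flagged invalid so that downstream quantifications exclude them rather
#' than fabricate signal.  The z voxel size is
#' \code{section_thickness * interleave}.
#'
#' @param series a [section_series()].
#' @param target_xy_resolution optional in-plane resolution (um/px) to
#'   uniformly rescale all images to before stacking.
#' @param modality modality tag for the output; defaults to
#'   \code{"histology"} for RGB input and \code{"blockface"} for grayscale.
#' @return a [volume()] with \code{dz = section_thickness * interleave} and
#'   \code{valid_planes} flagging the gap planes \code{FALSE}.
#' @export
stack_sections <- function(series, target_xy_resolution = NULL,
                           modality = NULL) {
  stopifnot(inherits(series, "section_series"))
  imgs <- series$images
  dims <- lapply(imgs, function(im) dim(im)[1:2])
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    .h3d_stop("h3d_shape_error", "section images have inconsistent pixel dimensions")
  res <- series$in_plane_resolution
  if (!is.null(target_xy_resolution) && target_xy_resolution != res) {
    f <- res / target_xy_resolution
    nd <- round(dims[[1]] * f)
    idt <- affine2d()                       # identity in world coords
    imgs <- lapply(imgs, function(im)
      resample_image(im, idt, pixel_size = target_xy_resolution,
                     target_dim = nd, mode = "linear"))
    res <- target_xy_resolution
  }
  rgb <- length(dim(imgs[[1]])) == 3L
  if (is.null(modality)) modality <- if (rgb) "histology" else "blockface"
  nz <- max(series$z_indices) + 1L
  d2 <- dim(imgs[[1]])[1:2]
  data <- if (rgb) array(0, c(d2, nz, 3L)) else array(0, c(d2, nz))
  valid <- rep(FALSE, nz)
  for (i in seq_along(imgs)) {
    z <- series$z_indices[i] + 1L
    if (rgb) data[, , z, ] <- imgs[[i]] else data[, , z] <- imgs[[i]]
    valid[z] <- TRUE
  }
  dz <- series$section_thickness * series$interleave
  volume(data, c(res, res, dz), modality, valid_planes = valid)
}

#' Extract one plane of a volume as an image
#' @param vol a [volume()].
#' @param z 0-based plane index.
#' @export
get_plane <- function(vol, z) {
  d <- dim(vol$data)
  if (z < 0 || z >= d[3]) .h3d_stop("h3d_value_error", "plane %d out of range", z)
  if (length(d) == 4L) vol$data[, , z + 1L, , drop = TRUE] else vol$data[, , z + 1L]
}
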