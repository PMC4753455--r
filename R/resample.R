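#' Resample a volume through a transform
#'
#' Pull-back resampling: each voxel of the target grid is mapped through the
#' transform into the source volume's world space and interpolated there.
#' Use \code{mode = "nearest"} for label and mask volumes (never creates
#' label values absent from the input) and \code{"linear"} for intensities
#' and heat maps.
#'
#' @param vol source [volume()].
#' @param t transform mapping target world coordinates (um) to source world
#'   coordinates; use [affine3d()] / [rigid3d()] / [ffd3d()] or a composite.
#' @param target_grid either a [volume()] whose geometry is copied, or a list
#'   \code{list(dim = c(nx, ny, nz), voxel_size = c(dx, dy, dz))}.
#' @param mode \code{"linear"} or \code{"nearest"}; default nearest for label
#'   and mask sources, linear otherwise.
#' @param background fill value for voxels mapping outside the source field
#'   of view (default 0).
#' @return a [volume()] on the target grid, same modality as the source.
#' @export
resample <- function(vol, t, target_grid = vol, mode = NULL, background = 0) {
  stopifnot(is_volume(vol))
  if (is_volume(target_grid))
    target_grid <- list(dim = dim(target_grid$data)[1:3],
                        voxel_size = unname(target_grid$voxel_size))
  td <- as.integer(target_grid$dim)
  tvs <- as.numeric(target_grid$voxel_size)
  if (is.null(mode))
    mode <- if (vol$modality %in% c("label", "mask")) "nearest" else "linear"
  imode <- match(mode, c("linear", "nearest")) - 1L
  dummy <- volume(array(0, td), tvs, "mask")
  pts <- voxel_centers(dummy)
  src <- apply_transform(t, pts)
  d <- dim(vol$data)
  if (length(d) == 4L) {
    out <- array(0, c(td, 3L))
    for (ch in 1:3)
      out[, , , ch] <- array(.cpp_interp3(as.numeric(vol$data[, , , ch]), d[1:3],
                                          src, unname(vol$voxel_size),
                                          imode, 0L, background), td)
  } else {
    out <- array(.cpp_interp3(as.numeric(vol$data), d, src,
                              unname(vol$voxel_size), imode, 0L, background), td)
  }
  if (vol$modality == "label") out <- round(out)
  volume(out, tvs, vol$modality)
}

#' Resample a 2D image through a 2D affine transform
#'
#' @param img matrix (grayscale) or \code{(nx, ny, 3)} array (RGB).
#' @param t an [affine2d()] mapping target world coords to source world
#'   coords (pull-back).
#' @param pixel_size in-plane resolution (um/px), scalar or length 2.
#' @param target_dim output pixel dims; defaults to the input dims.
#' @param mode \code{"linear"} or \code{"nearest"}.
#' @param background fill value outside the source image.
#' @export
resample_image <- function(img, t, pixel_size, target_dim = NULL,
                           mode = "linear", background = 0) {
  pixel_size <- rep(as.numeric(pixel_size), length.out = 2)
  d <- dim(img)
  if (is.null(target_dim)) target_dim <- d[1:2]
  imode <- match(mode, c("linear", "nearest")) - 1L
  xs <- (seq_len(target_dim[1]) - 0.5) * pixel_size[1]
  ys <- (seq_len(target_dim[2]) - 0.5) * pixel_size[2]
  pts <- cbind(rep(xs, times = target_dim[2]), rep(ys, each = target_dim[1]))
  src <- apply_transform(t, pts)
  if (length(d) == 3L) {
    out <- array(0, c(target_dim, 3L))
    for (ch in 1:3)
      out[, , ch] <- matrix(.cpp_interp2(img[, , ch], src, pixel_size,
                                         imode, 0L, background), target_dim[1])
    out
  } else {
    matrix(.cpp_interp2(img, src, pixel_size, imode, 0L, background),
           target_dim[1])
  }
}
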