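#' Write a volume to NIfTI-1
#'
#' Voxel sizes are written to the NIfTI header in millimetres
#' (\code{um * 1e-3}); a sidecar JSON next to the file records the original
#' micrometre units, the modality and the per-plane validity flags so that a
#' round trip restores the object exactly.  Label and mask volumes are
#' stored as integers.
#'
#' @param vol a [volume()].
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @return the path, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_volume(vol))
  arr <- vol$data
  if (vol$modality %in% c("label", "mask")) storage.mode(arr) <- "integer"
  pd <- unname(vol$voxel_size) * 1e-3
  if (length(dim(arr)) == 4L) pd <- c(pd, 1)
  img <- RNifti::asNifti(arr, pixdim = pd)
  RNifti::writeNifti(img, path)
  side <- list(units = "um", voxel_size_um = unname(vol$voxel_size),
               modality = vol$modality, valid_planes = vol$valid_planes)
  jsonlite::write_json(side, .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.sidecar_path <- function(path)
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")

#' Read a volume written by [write_volume()]
#'
#' Without a sidecar JSON the voxel sizes are taken from the NIfTI header
#' (mm, converted to um) and the modality defaults to \code{"mri"}.
#'
#' @param path NIfTI path.
#' @param modality override the modality tag.
#' @export
read_volume <- function(path, modality = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))   # drop NIfTI header attributes
  side_path <- .sidecar_path(path)
  if (file.exists(side_path)) {
    side <- jsonlite::fromJSON(side_path)
    vs <- side$voxel_size_um
    if (is.null(modality)) modality <- side$modality
    vp <- side$valid_planes
  } else {
    vs <- RNifti::pixdim(img)[1:3] * 1e3
    if (is.null(modality)) modality <- "mri"
    vp <- NULL
  }
  volume(arr, vs, modality, valid_planes = vp)
}

.img_to_png <- function(img) {
  # internal (nx, ny[, 3]) 0-255 -> writePNG's (row = y, col = x) in [0, 1]
  if (length(dim(img)) == 3L) aperm(img, c(2, 1, 3)) / 255 else t(img) / 255
}

.png_to_img <- function(arr) {
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] > 3L) arr <- arr[, , 1:3, drop = FALSE]  # drop alpha
    if (dim(arr)[3] == 1L) return(t(arr[, , 1]) * 255)
    aperm(arr, c(2, 1, 3)) * 255
  } else t(arr) * 255
}

#' Write a section series to a directory of PNGs
#'
#' One PNG per section (\code{section_0000.png}, numbered by block-face
#' plane index) plus a \code{manifest.json} with the sampling design.
#'
#' @param series a [section_series()].
#' @param dir output directory (created if needed).
#' @param format \code{"png"} (one file per section) or \code{"tiff"}
#'   (single multi-page TIFF \code{sections.tif}).
#' @export
write_section_series <- function(series, dir, format = c("png", "tiff")) {
  format <- match.arg(format)
  stopifnot(inherits(series, "section_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (format == "png") {
    files <- sprintf("section_%04d.png", series$z_indices)
    for (i in seq_along(series$images))
      png::writePNG(.img_to_png(series$images[[i]]), file.path(dir, files[i]))
  } else {
    files <- "sections.tif"
    tiff::writeTIFF(lapply(series$images, .img_to_png),
                    file.path(dir, files), bits.per.sample = 8L)
  }
  manifest <- list(format = format, files = files,
                   z_indices = series$z_indices,
                   in_plane_resolution_um = series$in_plane_resolution,
                   section_thickness_um = series$section_thickness,
                   interleave = series$interleave)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a section series written by [write_section_series()]
#' @param dir directory containing the images and \code{manifest.json}.
#' @export
read_section_series <- function(dir) {
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  imgs <- if (identical(man$format, "tiff")) {
    lapply(tiff::readTIFF(file.path(dir, man$files), all = TRUE), .png_to_img)
  } else {
    lapply(file.path(dir, man$files), function(f) .png_to_img(png::readPNG(f)))
  }
  section_series(imgs, man$z_indices, man$in_plane_resolution_um,
                 man$section_thickness_um, man$interleave)
}
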