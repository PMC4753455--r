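#' Otsu threshold of an intensity sample
#'
#' Maximizes the between-class variance of the intensity histogram; the
#' returned value separates the two histogram modes.
#'
#' @param x numeric vector or array of intensities.
#' @param n_bins histogram resolution.
#' @return scalar threshold; values strictly above it are "bright".
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  rng <- range(x, finite = TRUE)
  if (!all(is.finite(rng)) || diff(rng) <= 0)
    .h3d_stop("h3d_degenerate_threshold",
              "constant-intensity input: no threshold separates tissue from background")
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- as.numeric(tabulate(findInterval(x, br, rightmost.closed = TRUE), n_bins))
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- cumsum(h)
  n <- w[n_bins]
  m <- cumsum(h * mids)
  mt <- m[n_bins]
  valid <- w > 0 & w < n
  if (!any(valid))
    .h3d_stop("h3d_degenerate_threshold", "degenerate histogram: single occupied bin")
  between <- rep(-Inf, n_bins)
  between[valid] <- (mt * w[valid] - m[valid] * n)^2 /
    (w[valid] * (n - w[valid]))
  mids[which.max(between)]
}

#' Automatic tissue mask of a block-face volume
#'
#' Separates tissue from background with an automatic histogram threshold
#' (Otsu's criterion).  For RGB block-face photographs the channel with
#' maximal tissue/background contrast can be selected; the default operates
#' on luminance.
#'
#' @param vol a block-face [volume()], grayscale or RGB.
#' @param tissue which side of the threshold is tissue: \code{"bright"}
#'   (default) or \code{"dark"}.
#' @param channel for RGB input: \code{"luminance"} (default), \code{"r"},
#'   \code{"g"}, \code{"b"}, or \code{"auto"} (channel with the largest Otsu
#'   between-class separation).
#' @return a mask [volume()] (1 = tissue), same grid and validity flags.
#' @export
auto_mask_blockface <- function(vol, tissue = c("bright", "dark"),
                                channel = c("luminance", "r", "g", "b", "auto")) {
  stopifnot(is_volume(vol))
  if (vol$modality != "blockface")
    .h3d_stop("h3d_value_error", "auto_mask_blockface expects a blockface volume")
  tissue <- match.arg(tissue)
  channel <- match.arg(channel)
  d <- dim(vol$data)
  if (length(d) == 4L) {
    gray <- switch(channel,
      luminance = (vol$data[, , , 1] + vol$data[, , , 2] + vol$data[, , , 3]) / 3,
      r = vol$data[, , , 1], g = vol$data[, , , 2], b = vol$data[, , , 3],
      auto = {
        seps <- vapply(1:3, function(ch) {
          x <- vol$data[, , , ch]
          th <- try(otsu_threshold(x), silent = TRUE)
          if (inherits(th, "try-error")) return(-Inf)
          abs(mean(x[x > th]) - mean(x[x <= th]))
        }, numeric(1))
        vol$data[, , , which.max(seps)]
      })
  } else gray <- vol$data
  th <- otsu_threshold(gray)
  m <- if (tissue == "bright") gray > th else gray <= th
  volume(array(as.numeric(m), d[1:3]), unname(vol$voxel_size), "mask",
         valid_planes = vol$valid_planes)
}

#' Zero out background voxels of a volume
#' @param vol a [volume()].
#' @param mask a mask [volume()] on the same grid.
#' @export
apply_mask <- function(vol, mask) {
  stopifnot(is_volume(vol), is_volume(mask), mask$modality == "mask")
  d <- dim(vol$data)
  if (!identical(dim(mask$data), d[1:3]))
    .h3d_stop("h3d_shape_error", "mask grid does not match volume grid")
  out <- vol
  if (length(d) == 4L) {
    for (ch in 1:3) out$data[, , , ch] <- out$data[, , , ch] * mask$data
  } else out$data <- out$data * mask$data
  out
}
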