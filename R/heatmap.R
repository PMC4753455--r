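#' Occupancy heat map from a high-resolution segmentation
#'
#' Aggregates the binary high-resolution segmentation in x and y (and, when
#' needed, z) into low-resolution voxels (default 125 um isotropic) whose
#' value is the staining occupation ratio: stained high-res voxels divided
#' by covered high-res voxels.  Invalid planes are excluded from the
#' denominator; partially covered boundary voxels use the covered-voxel
#' denominator so the brain rim is not underestimated.  A brain mask at
#' heat-map resolution flags voxels with at least half their support in
#' tissue (when a tissue mask is supplied) for use in correlations.
#'
#' @param seg binary mask [volume()] (high resolution).
#' @param target_size target voxel edge in um (default 125, isotropic); must
#'   be an integer multiple of the in-plane voxel sizes.
#' @param tissue_mask optional tissue mask [volume()] on the grid of
#'   \code{seg}, used to build the heat-map brain mask.
#' @return a [volume()] of modality \code{"heatmap"} carrying extra fields:
#'   \code{$brain_mask}, \code{$smoothed = FALSE}, \code{$stained_counts}
#'   and \code{$covered_counts} (the exact integer numerators/denominators).
#' @export
occupancy_heatmap <- function(seg, target_size = 125, tissue_mask = NULL) {
  stopifnot(is_volume(seg))
  vs <- unname(seg$voxel_size)
  fx <- target_size / vs[1]; fy <- target_size / vs[2]
  if (abs(fx - round(fx)) > 1e-9 || abs(fy - round(fy)) > 1e-9) {
    sug <- ceiling(target_size / vs[1]) * vs[1]
    .h3d_stop("h3d_resolution_error",
              "target size %g um is not an integer multiple of the in-plane voxel size (%g x %g um); try %g um",
              target_size, vs[1], vs[2], sug)
  }
  fx <- as.integer(round(fx)); fy <- as.integer(round(fy))
  d <- dim(seg$data)[1:3]
  nzo <- d[3]
  # z handling: reconstructed dz is often already the target; otherwise
  # average whole planes into target slabs with plane-validity weights
  fz <- target_size / vs[3]
  zplan <- if (abs(fz - 1) < 1e-9) {
    list(starts = seq_len(nzo), ends = seq_len(nzo))
  } else {
    nz_t <- max(1L, as.integer(ceiling(d[3] * vs[3] / target_size)))
    s <- floor((seq_len(nz_t) - 1L) * target_size / vs[3]) + 1L
    e <- pmin(ceiling(seq_len(nz_t) * target_size / vs[3]), d[3])
    list(starts = s, ends = e)
  }
  nx_t <- as.integer(ceiling(d[1] / fx)); ny_t <- as.integer(ceiling(d[2] / fy))
  nz_t <- length(zplan$starts)
  block_sum_xy <- function(m) {
    # sum an nx x ny matrix over fx x fy tiles (partial tiles at the edges)
    gi <- (seq_len(nrow(m)) - 1L) %/% fx + 1L
    gj <- (seq_len(ncol(m)) - 1L) %/% fy + 1L
    rowsum_i <- rowsum(m, gi)
    t(rowsum(t(rowsum_i), gj))
  }
  stained <- array(0, c(nx_t, ny_t, nz_t))
  covered <- array(0, c(nx_t, ny_t, nz_t))
  tiss <- array(0, c(nx_t, ny_t, nz_t))
  ones <- matrix(1, d[1], d[2])
  cover_plane <- block_sum_xy(ones)
  for (zt in seq_len(nz_t)) {
    for (z in zplan$starts[zt]:zplan$ends[zt]) {
      if (!seg$valid_planes[z]) next
      stained[, , zt] <- stained[, , zt] + block_sum_xy(seg$data[, , z])
      covered[, , zt] <- covered[, , zt] + cover_plane
      if (!is.null(tissue_mask))
        tiss[, , zt] <- tiss[, , zt] + block_sum_xy(tissue_mask$data[, , z])
    }
  }
  hm <- ifelse(covered > 0, stained / pmax(covered, 1), 0)
  out <- volume(hm, c(vs[1] * fx, vs[2] * fy,
                      if (abs(fz - 1) < 1e-9) vs[3] else target_size),
                "heatmap", valid_planes = apply(covered, 3, sum) > 0)
  out$brain_mask <- if (is.null(tissue_mask)) {
    array(as.numeric(covered > 0), dim(covered))
  } else array(as.numeric(covered > 0 & tiss >= 0.5 * covered), dim(covered))
  out$smoothed <- FALSE
  out$stained_counts <- stained
  out$covered_counts <- covered
  class(out) <- c("heatmap", class(out))
  out
}

.gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

.conv_axis <- function(arr, k, axis) {
  r <- (length(k) - 1L) / 2
  out <- array(0, dim(arr))
  d <- dim(arr)
  for (i in seq_along(k)) {
    off <- i - r - 1L
    src <- seq_len(d[axis]) + off
    ok <- src >= 1L & src <= d[axis]
    if (!any(ok)) next
    idx_dst <- which(ok); idx_src <- src[ok]
    if (axis == 1L) out[idx_dst, , ] <- out[idx_dst, , ] + k[i] * arr[idx_src, , ]
    else if (axis == 2L) out[, idx_dst, ] <- out[, idx_dst, ] + k[i] * arr[, idx_src, ]
    else out[, , idx_dst] <- out[, , idx_dst] + k[i] * arr[, , idx_src]
  }
  out
}

#' Gaussian smoothing of a heat map
#'
#' Separable Gaussian filter in x, y and z with a kernel matched to the
#' heat-map voxel size: by default the standard deviation is one heat-map
#' voxel per axis (\code{kernel = "sigma"}); \code{kernel = "fwhm"} instead
#' sets the full width at half maximum to one voxel.  Smoothing is
#' mask-normalized -- the filtered numerator is divided by the filtered
#' brain mask -- so no staining mass bleeds outside the brain and a constant
#' heat map is left unchanged inside the mask.
#'
#' @param hm a heat map from [occupancy_heatmap()], not yet smoothed.
#' @param kernel \code{"sigma"} (default) or \code{"fwhm"}.
#' @return the smoothed heat map (\code{$smoothed = TRUE}), values clipped
#'   to \code{[0, 1]}.
#' @export
smooth_heatmap <- function(hm, kernel = c("sigma", "fwhm")) {
  stopifnot(inherits(hm, "heatmap"))
  if (isTRUE(hm$smoothed))
    .h3d_stop("h3d_value_error", "heat map is already smoothed")
  kernel <- match.arg(kernel)
  sigma <- if (kernel == "sigma") 1 else 1 / (2 * sqrt(2 * log(2)))
  k <- .gauss_kernel(sigma)
  m <- hm$brain_mask
  num <- hm$data * m
  den <- m
  for (ax in 1:3) {
    num <- .conv_axis(num, k, ax)
    den <- .conv_axis(den, k, ax)
  }
  sm <- ifelse(den > 1e-12, num / den, 0) * (m > 0)
  out <- hm
  out$data <- pmin(pmax(sm, 0), 1)
  out$smoothed <- TRUE
  out
}

#' Voxel-wise Spearman correlation of two heat maps
#'
#' Assesses the spatial dependence of two markers by rank-correlating their
#' heat-map voxel values over the (masked) brain, with average ranks for
#' ties and a two-sided p value.
#'
#' @param hm_a,hm_b heat maps on the same grid.
#' @param mask optional 0/1 array; defaults to the intersection of the two
#'   brain masks.
#' @return \code{list(rho, p_value, n_voxels)}.
#' @export
correlate_heatmaps <- function(hm_a, hm_b, mask = NULL) {
  stopifnot(is_volume(hm_a), is_volume(hm_b))
  if (!identical(dim(hm_a$data), dim(hm_b$data)))
    .h3d_stop("h3d_shape_error", "heat maps are on different grids")
  if (is.null(mask)) {
    ma <- if (!is.null(hm_a$brain_mask)) hm_a$brain_mask else array(1, dim(hm_a$data))
    mb <- if (!is.null(hm_b$brain_mask)) hm_b$brain_mask else array(1, dim(hm_b$data))
    mask <- ma * mb
  } else if (is_volume(mask)) mask <- mask$data
  a <- hm_a$data[mask > 0]; b <- hm_b$data[mask > 0]
  if (length(a) < 3L)
    .h3d_stop("h3d_value_error", "need at least 3 masked voxels")
  if (length(unique(a)) < 2L || length(unique(b)) < 2L)
    .h3d_stop("h3d_undefined_correlation",
              "constant heat map: rank correlation undefined")
  ct <- suppressWarnings(cor.test(a, b, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n_voxels = length(a))
}
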