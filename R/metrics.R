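#' Pearson correlation coefficient of two images or volumes
#'
#' The similarity criterion maximized by the block-matching registrations.
#'
#' @param a,b numeric arrays of identical shape, or [volume()] objects.
#' @param mask optional logical/0-1 array restricting the comparison.
#' @return scalar in \code{[-1, 1]}.
#' @export
correlation_coefficient <- function(a, b, mask = NULL) {
  a <- if (is_volume(a)) a$data else a
  b <- if (is_volume(b)) b$data else b
  if (!identical(dim(a), dim(b)))
    .h3d_stop("h3d_shape_error", "inputs have different shapes")
  if (!is.null(mask)) {
    mask <- if (is_volume(mask)) mask$data else mask
    a <- a[mask > 0]; b <- b[mask > 0]
  }
  if (length(a) < 2L)
    .h3d_stop("h3d_value_error", "need at least 2 voxels to correlate")
  if (sd(a) == 0 || sd(b) == 0)
    .h3d_stop("h3d_undefined_metric",
              "zero variance: correlation coefficient undefined")
  cor(as.numeric(a), as.numeric(b))
}

.joint_hist <- function(a, b, n_bins, a_range = range(a), b_range = range(b)) {
  ba <- .bin_values(a, n_bins, a_range)
  bb <- .bin_values(b, n_bins, b_range)
  matrix(tabulate(ba + n_bins * (bb - 1L), n_bins * n_bins), n_bins, n_bins)
}

.bin_values <- function(x, n_bins, rng) {
  if (diff(rng) <= 0) return(rep(1L, length(x)))
  i <- as.integer(floor((x - rng[1]) / diff(rng) * n_bins)) + 1L
  pmin(pmax(i, 1L), n_bins)
}

.mi_from_hist <- function(H) {
  n <- sum(H)
  p <- H / n
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(px, py)[nz]))
}

#' Mutual information of two images or volumes (bits)
#'
#' MI of the joint intensity histogram, in bits (base-2 logarithm), the
#' similarity criterion for multimodal (rigid and elastic) registration.
#'
#' @param a,b numeric arrays of identical shape, or [volume()] objects.
#' @param n_bins histogram bins per axis (>= 2); default 64.
#' @param mask optional mask restricting the overlap (background excluded).
#' @return scalar, \code{>= 0}.
#' @export
mutual_information <- function(a, b, n_bins = 64L, mask = NULL) {
  a <- if (is_volume(a)) a$data else a
  b <- if (is_volume(b)) b$data else b
  if (!identical(dim(a), dim(b)))
    .h3d_stop("h3d_shape_error", "inputs have different shapes")
  if (n_bins < 2L) .h3d_stop("h3d_value_error", "n_bins must be >= 2")
  if (!is.null(mask)) {
    mask <- if (is_volume(mask)) mask$data else mask
    a <- a[mask > 0]; b <- b[mask > 0]
  }
  if (length(a) == 0L)
    .h3d_stop("h3d_value_error", "empty overlap: mutual information undefined")
  .mi_from_hist(.joint_hist(as.numeric(a), as.numeric(b), as.integer(n_bins)))
}
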