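#' Rostro-caudal load profile of an ROI
#'
#' Per-section staining load (percent of ROI voxels stained on that coronal
#' plane) along the rostro-caudal (z) axis, with the mean, sample (n-1)
#' standard deviation and coefficient of variation \code{CV = 100 * sd /
#' mean} describing the dispersion of the marker along the axis.  Sections
#' where the ROI is absent, and invalid planes, are excluded (not zero).
#'
#' @param seg binary mask [volume()].
#' @param labels label [volume()] on the same grid.
#' @param roi_labels integer label values forming the ROI.
#' @return \code{list(z_index, load_pct, mean, sd, cv)}; \code{z_index} is
#'   0-based.
#' @export
rostrocaudal_profile <- function(seg, labels, roi_labels) {
  stopifnot(is_volume(seg), is_volume(labels))
  if (!identical(dim(seg$data)[1:3], dim(labels$data)[1:3]))
    .h3d_stop("h3d_shape_error", "segmentation and labels are on different grids")
  nz <- dim(seg$data)[3]
  valid <- seg$valid_planes & labels$valid_planes
  zs <- integer(0); loads <- numeric(0)
  for (z in seq_len(nz)) {
    if (!valid[z]) next
    roi <- labels$data[, , z] %in% roi_labels
    n_roi <- sum(roi)
    if (n_roi == 0L) next
    zs <- c(zs, z - 1L)
    loads <- c(loads, 100 * sum(seg$data[, , z][roi] > 0) / n_roi)
  }
  if (length(loads) == 0L)
    .h3d_stop("h3d_empty_roi", "ROI absent from every valid section")
  m <- mean(loads)
  s <- if (length(loads) > 1L) sd(loads) else 0
  if (m == 0)
    .h3d_stop("h3d_undefined_cv", "mean load is zero: CV undefined")
  list(z_index = zs, load_pct = loads, mean = m, sd = s, cv = 100 * s / m)
}

#' Equidistant section subsets at a sampling period
#'
#' All phase offsets of a 1-in-k sampling of the valid section list: one
#' subset per offset \code{o in 0..k-1}, taking positions \code{o, o+k,
#' o+2k, ...} within the ordered list.  Empty subsets are dropped, so
#' \code{k > n} yields n singleton subsets.  Subsets are pairwise disjoint
#' and their union is the full list.
#'
#' @param valid_sections ordered vector of section indices.
#' @param step_k sampling period (>= 1).
#' @return list of vectors of section indices.
#' @export
enumerate_subsets <- function(valid_sections, step_k) {
  step_k <- as.integer(step_k)
  if (step_k < 1L) .h3d_stop("h3d_value_error", "step_k must be >= 1")
  n <- length(valid_sections)
  out <- lapply(seq_len(step_k) - 1L, function(o) {
    if (o + 1L > n) return(valid_sections[integer(0)])
    valid_sections[seq(o + 1L, n, by = step_k)]
  })
  out[vapply(out, length, integer(1)) > 0L]
}

#' Relative error of a subset quantification
#'
#' \code{RE = 100 * |L_subset - L_full| / L_full}, the percentage deviation
#' of a sparse-sampling load estimate from the all-sections reference.
#'
#' @param l_subset subset load (percent).
#' @param l_full reference load (percent), must be > 0.
#' @export
relative_error <- function(l_subset, l_full) {
  if (any(l_full <= 0))
    .h3d_stop("h3d_undefined_reference",
              "reference load must be > 0 for a relative error")
  100 * abs(l_subset - l_full) / l_full
}

#' Section-sampling simulation
#'
#' Emulates sparse 2D quantification protocols on the full 3D data:
#' progressively discards equidistant sections at each sampling period k,
#' forms every phase-offset subset, quantifies the ROI load on each subset
#' (pooled counts over the subset's sections, as 2D protocols pool outlined
#' areas) and reports its relative error against the all-sections 3D
#' reference.
#'
#' @param seg binary mask [volume()].
#' @param labels label [volume()] on the same grid.
#' @param roi_labels integer label values forming the ROI.
#' @param steps sampling periods k to simulate.
#' @return data.frame with columns \code{k}, \code{spacing_mm}, \code{offset}
#'   (0-based), \code{n_sections}, \code{load_subset_pct}, \code{load_full_pct},
#'   \code{relative_error_pct}; per-k medians/quartiles in
#'   \code{attr(, "summary")}.
#' @export
sampling_simulation <- function(seg, labels, roi_labels, steps = c(1, 5, 10, 15)) {
  stopifnot(is_volume(seg), is_volume(labels))
  nz <- dim(seg$data)[3]
  valid <- seg$valid_planes & labels$valid_planes
  roi_n <- integer(nz); st_n <- integer(nz)
  for (z in seq_len(nz)) {
    if (!valid[z]) next
    roi <- labels$data[, , z] %in% roi_labels
    roi_n[z] <- sum(roi)
    st_n[z] <- sum(seg$data[, , z][roi] > 0)
  }
  sections <- which(roi_n > 0)          # 1-based plane indices with ROI
  if (length(sections) == 0L)
    .h3d_stop("h3d_empty_roi", "ROI absent from every valid section")
  l_full <- 100 * sum(st_n[sections]) / sum(roi_n[sections])
  if (l_full <= 0)
    .h3d_stop("h3d_undefined_reference", "reference load is zero")
  dz_mm <- unname(seg$voxel_size[3]) * 1e-3
  rows <- list()
  for (k in steps) {
    subs <- enumerate_subsets(sections, k)
    for (o in seq_along(subs)) {
      s <- subs[[o]]
      l_sub <- 100 * sum(st_n[s]) / sum(roi_n[s])
      rows[[length(rows) + 1L]] <- data.frame(
        k = k, spacing_mm = k * dz_mm, offset = o - 1L,
        n_sections = length(s), load_subset_pct = l_sub,
        load_full_pct = l_full,
        relative_error_pct = relative_error(l_sub, l_full))
    }
  }
  out <- do.call(rbind, rows)
  smry <- do.call(rbind, lapply(split(out, out$k), function(g)
    data.frame(k = g$k[1], spacing_mm = g$spacing_mm[1],
               n_subsets = nrow(g),
               median_re = median(g$relative_error_pct),
               q1_re = unname(quantile(g$relative_error_pct, 0.25)),
               q3_re = unname(quantile(g$relative_error_pct, 0.75)))))
  attr(out, "summary") <- smry[order(smry$k), , drop = FALSE]
  out
}

#' Two-group comparison of regional loads
#'
#' Two-sided Mann-Whitney U test (Wilcoxon rank-sum) with average ranks for
#' ties, the nonparametric comparison used for between-group load
#' differences.
#'
#' @param loads_a,loads_b numeric vectors of per-animal loads.
#' @return \code{list(u, p_value, n_a, n_b)} where \code{u} is the
#'   Mann-Whitney U statistic of the first group.
#' @export
compare_groups <- function(loads_a, loads_b) {
  if (length(loads_a) == 0L || length(loads_b) == 0L)
    .h3d_stop("h3d_value_error", "both groups must be nonempty")
  wt <- suppressWarnings(wilcox.test(loads_a, loads_b, exact = FALSE,
                                     correct = TRUE))
  list(u = unname(wt$statistic), p_value = wt$p.value,
       n_a = length(loads_a), n_b = length(loads_b))
}
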