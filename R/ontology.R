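#' Hierarchical anatomical ontology
#'
#' A strict tree of named anatomical nodes in the NeuroNames style; leaf
#' nodes carry the atlas label values they cover.  Every atlas label must
#' map to exactly one leaf.
#'
#' @param x a nested list \code{list(name, acronym, labels, children)}
#'   (labels only on leaves), e.g. parsed from JSON.
#' @return an object of class \code{"ontology"}.
#' @export
as_ontology <- function(x) {
  seen <- integer(0)
  check <- function(node, path) {
    if (is.null(node$name)) .h3d_stop("h3d_value_error", "ontology node without a name")
    kids <- node$children
    if (is.null(kids) || length(kids) == 0L) {
      labs <- as.integer(unlist(node$labels))
      if (length(labs) == 0L)
        .h3d_stop("h3d_value_error", "leaf node '%s' carries no atlas labels", node$name)
      dup <- intersect(labs, seen)
      if (length(dup))
        .h3d_stop("h3d_value_error",
                  "atlas label(s) %s mapped by more than one leaf",
                  paste(dup, collapse = ", "))
      seen <<- c(seen, labs)
    } else {
      if (!is.null(node$labels) && length(node$labels))
        .h3d_stop("h3d_value_error",
                  "internal node '%s' must not carry labels", node$name)
      for (k in kids) check(k, c(path, node$name))
    }
  }
  check(x, character(0))
  structure(x, class = "ontology")
}

#' Read an ontology from a JSON tree
#' @param path JSON file \code{\{name, acronym, labels[], children[]\}}.
#' @export
read_ontology <- function(path) {
  as_ontology(jsonlite::fromJSON(path, simplifyVector = FALSE,
                                 simplifyDataFrame = FALSE))
}

#' All atlas labels covered by an ontology (or subtree)
#' @param node an [as_ontology()] tree or any of its nodes.
#' @export
ontology_labels <- function(node) {
  if (is.null(node$children) || length(node$children) == 0L)
    return(as.integer(unlist(node$labels)))
  unlist(lapply(node$children, ontology_labels))
}

#' @export
print.ontology <- function(x, ...) {
  rec <- function(node, depth) {
    leaf <- is.null(node$children) || length(node$children) == 0L
    cat(strrep("  ", depth), node$name,
        if (!is.null(node$acronym)) sprintf(" (%s)", node$acronym) else "",
        if (leaf) sprintf(" [%s]", paste(unlist(node$labels), collapse = ",")) else "",
        "\n", sep = "")
    for (k in node$children) rec(k, depth + 1L)
  }
  rec(x, 0L)
  invisible(x)
}

#' Atlas-based parcellation of a block-face volume
#'
#' Registers the atlas intensity volume onto the block-face volume by the
#' three-stage chain rigid (mutual information, direction-set optimizer),
#' affine (block matching, correlation coefficient) and free-form
#' deformation (mutual information, quasi-Newton), then pulls the atlas
#' labels onto the block-face grid with nearest-neighbour resampling, which
#' never creates labels absent from the atlas.
#'
#' @param atlas_intensity anatomical atlas [volume()] (MRI-like contrast).
#' @param atlas_labels integer label [volume()] aligned with the intensity
#'   atlas.
#' @param blockface masked block-face [volume()], the registration
#'   reference.
#' @param ffd_grid control lattice of the elastic stage (default 10^3);
#'   \code{NULL} skips the elastic stage.
#' @param coarsen integer downsampling factor applied to both volumes for
#'   transform estimation (estimation-only; labels are resampled at full
#'   resolution).
#' @param affine_block_size block edge of the affine stage's block matching;
#'   small blocks reduce the scale bias that large multi-boundary blocks
#'   incur on cross-modal pairs.
#' @param ... passed to [register_ffd()].
#' @return \code{list(labels, transform, reports)}: the label [volume()] on
#'   the block-face grid and the per-stage registration reports.
#' @export
parcellate <- function(atlas_intensity, atlas_labels, blockface,
                       ffd_grid = c(10, 10, 10), coarsen = 1L,
                       affine_block_size = 5L, ...) {
  stopifnot(is_volume(atlas_intensity), is_volume(atlas_labels),
            is_volume(blockface))
  if (!identical(dim(atlas_labels$data)[1:3], dim(atlas_intensity$data)[1:3]))
    .h3d_stop("h3d_shape_error", "atlas labels not aligned with atlas intensity")
  shrink <- function(v, f) {
    if (f <= 1L) return(v)
    d <- dim(v$data)[1:3] %/% f
    grid <- list(dim = d, voxel_size = unname(v$voxel_size) * f)
    resample(v, affine3d(), grid, mode = "linear")
  }
  # mask the atlas to its labelled support so both volumes show the same
  # sharp brain/background edge; otherwise the differing edge profiles bias
  # the block-matching scale estimate
  atlas_masked <- atlas_intensity
  atlas_masked$data <- atlas_masked$data * (atlas_labels$data > 0L)
  ref <- shrink(blockface, coarsen)
  flo <- shrink(atlas_masked, coarsen)
  rig <- register_rigid_3d(ref, flo)
  aff <- register_affine_3d(ref, flo, init = rig$transform,
                            block_size = affine_block_size)
  reports <- list(rigid = rig$report, affine = aff$report)
  if (!is.null(ffd_grid)) {
    ffd <- register_ffd(ref, flo, init = aff$transform,
                        grid_shape = ffd_grid, ...)
    t_final <- ffd$transform
    reports$ffd <- ffd$report
  } else t_final <- aff$transform
  labels <- resample(atlas_labels, t_final, blockface, mode = "nearest")
  labels$valid_planes <- blockface$valid_planes
  list(labels = labels, transform = t_final, reports = reports)
}

#' Staining load within a region of interest
#'
#' Load is the percentage of the ROI volume occupied by segmented staining.
#' Planes flagged invalid (missing sections) are excluded from both counts.
#'
#' @param seg binary segmentation mask [volume()].
#' @param labels label [volume()] on the same grid.
#' @param roi_labels integer label values forming the ROI.
#' @param name optional region name attached to the result.
#' @return \code{list(name, region_volume_mm3, stained_volume_mm3,
#'   load_pct, n_roi_voxels, n_stained_voxels)}.
#' @export
region_load <- function(seg, labels, roi_labels, name = NULL) {
  stopifnot(is_volume(seg), is_volume(labels))
  if (!identical(dim(seg$data)[1:3], dim(labels$data)[1:3]))
    .h3d_stop("h3d_shape_error", "segmentation and labels are on different grids")
  valid <- seg$valid_planes & labels$valid_planes
  vmask <- rep(valid, each = prod(dim(seg$data)[1:2]))
  roi <- (labels$data %in% roi_labels) & vmask
  n_roi <- sum(roi)
  if (n_roi == 0L)
    .h3d_stop("h3d_empty_roi", "ROI {%s} contains no valid voxels",
              paste(roi_labels, collapse = ","))
  n_st <- sum(seg$data[roi] > 0)
  vox_mm3 <- prod(seg$voxel_size) * 1e-9
  list(name = name,
       region_volume_mm3 = n_roi * vox_mm3,
       stained_volume_mm3 = n_st * vox_mm3,
       load_pct = 100 * n_st / n_roi,
       n_roi_voxels = n_roi, n_stained_voxels = n_st)
}

#' Hierarchical marker-load quantification
#'
#' Computes per-leaf stained and region voxel counts, then rolls them up the
#' ontology: an internal node's volumes are the exact sums over its
#' descendant leaves and its load is recomputed from those sums
#' (volume-weighted, never a plain mean of child loads).  Leaves absent from
#' the label volume are reported with zero volume and \code{NA} load; labels
#' not covered by the ontology trigger a coverage warning.
#'
#' @param seg binary segmentation mask [volume()].
#' @param labels label [volume()] on the same grid.
#' @param ontology an [as_ontology()] tree.
#' @return data.frame with one row per node: \code{path}, \code{name},
#'   \code{acronym}, \code{depth}, \code{is_leaf}, \code{n_roi_voxels},
#'   \code{n_stained_voxels}, \code{region_volume_mm3},
#'   \code{stained_volume_mm3}, \code{load_pct}.
#' @export
ontology_quantify <- function(seg, labels, ontology) {
  stopifnot(inherits(ontology, "ontology"))
  valid <- seg$valid_planes & labels$valid_planes
  vmask <- rep(valid, each = prod(dim(seg$data)[1:2]))
  lab <- as.integer(labels$data)
  lab[!vmask] <- -1L
  st <- seg$data > 0
  maxl <- max(lab, 0L)
  roi_counts <- tabulate(lab + 1L, maxl + 1L)          # counts for labels 0..maxl
  st_counts <- tabulate((lab + 1L)[st], maxl + 1L)
  count_of <- function(v, labs) sum(v[labs[labs + 1L <= length(v) & labs >= 0L] + 1L])
  covered <- ontology_labels(ontology)
  present <- setdiff(unique(lab[lab > 0L]), 0L)
  orphans <- setdiff(present, covered)
  if (length(orphans))
    warning(sprintf("labels not covered by the ontology: %s",
                    paste(sort(orphans), collapse = ", ")),
            call. = FALSE)
  vox_mm3 <- prod(seg$voxel_size) * 1e-9
  rows <- list()
  rec <- function(node, path, depth) {
    leaf <- is.null(node$children) || length(node$children) == 0L
    if (leaf) {
      labs <- as.integer(unlist(node$labels))
      n_roi <- count_of(roi_counts, labs)
      n_st <- count_of(st_counts, labs)
    } else {
      kid <- lapply(node$children, rec,
                    path = c(path, node$name), depth = depth + 1L)
      n_roi <- sum(vapply(kid, `[[`, numeric(1), "n_roi"))
      n_st <- sum(vapply(kid, `[[`, numeric(1), "n_st"))
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      path = paste(c(path, node$name), collapse = "/"),
      name = node$name,
      acronym = if (!is.null(node$acronym)) node$acronym else NA_character_,
      depth = depth, is_leaf = leaf,
      n_roi_voxels = n_roi, n_stained_voxels = n_st,
      region_volume_mm3 = n_roi * vox_mm3,
      stained_volume_mm3 = n_st * vox_mm3,
      load_pct = if (n_roi > 0) 100 * n_st / n_roi else NA_real_,
      stringsAsFactors = FALSE)
    list(n_roi = n_roi, n_st = n_st)
  }
  rec(ontology, character(0), 0L)
  out <- do.call(rbind, rows)
  out[order(out$path), , drop = FALSE]
}
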