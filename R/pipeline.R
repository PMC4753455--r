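#' Pipeline configuration
#'
#' Bundles every stage parameter of the end-to-end run with the
#' study-design defaults: 3 pyramid levels for section-to-block-face
#' registration, a 10 x 10 x 10 control lattice for the elastic atlas
#' registration, 125 um isotropic heat maps.
#'
#' @param out_dir output directory (created).
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @param phantom a [phantom_spec()]; by default one derived from
#'   \code{seed}.  Ignored when \code{dataset} is supplied.
#' @param dataset optionally a ready [make_phantom()] dataset (or one
#'   assembled from real inputs with the same structure).
#' @param pyramid_levels resolution levels of the 2D registrations.
#' @param search_radius block-search radius (px) of the 2D registrations.
#' @param bm_max_iter block-matching refinement iterations per level.
#' @param ffd_grid elastic atlas registration control lattice.
#' @param ffd_max_iter L-BFGS iteration cap of the elastic stage.
#' @param atlas_coarsen downsampling factor for atlas transform estimation.
#' @param heatmap_size heat-map voxel edge (um).
#' @param sampling_steps section-sampling periods simulated.
#' @param sampling_rois ontology leaf names simulated.
#' @param n_components,n_patches,holdout_patches classifier training:
#'   mixture components per class, training patches drawn, patches held out
#'   for F1 evaluation.
#' @param model_paths optional named list marker -> path of a serialized
#'   [write_biovision()] model to use instead of training.
#' @export
pipeline_config <- function(out_dir, seed = 0L, phantom = NULL,
                            dataset = NULL, pyramid_levels = 3L,
                            search_radius = 10L, bm_max_iter = 4L,
                            ffd_grid = c(10, 10, 10), ffd_max_iter = 30L,
                            atlas_coarsen = 2L, heatmap_size = 125,
                            sampling_steps = c(1, 5, 10, 15),
                            sampling_rois = c("cerebral_cortex", "thalamus"),
                            n_components = 3L, n_patches = 16L,
                            holdout_patches = 4L, model_paths = NULL) {
  if (is.null(phantom)) phantom <- phantom_spec(seed = seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 phantom = phantom, dataset = dataset,
                 pyramid_levels = as.integer(pyramid_levels),
                 search_radius = as.integer(search_radius),
                 bm_max_iter = as.integer(bm_max_iter),
                 ffd_grid = ffd_grid, ffd_max_iter = as.integer(ffd_max_iter),
                 atlas_coarsen = as.integer(atlas_coarsen),
                 heatmap_size = heatmap_size,
                 sampling_steps = sampling_steps,
                 sampling_rois = sampling_rois,
                 n_components = as.integer(n_components),
                 n_patches = as.integer(n_patches),
                 holdout_patches = as.integer(holdout_patches),
                 model_paths = model_paths),
            class = "pipeline_config")
}

.stage <- function(name, log_con, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  if (!is.null(log_con))
    writeLines(jsonlite::toJSON(list(stage = name,
                                     seconds = round(as.numeric(Sys.time() - t0,
                                                                units = "secs"), 2)),
                                auto_unbox = TRUE), log_con)
  res
}

#' Run the full analysis pipeline
#'
#' Executes the stage sequence stack, mask, reconstruct (per-marker
#' section-to-block-face registration), train + segment, atlas parcellation
#' (rigid, affine, elastic), ontology quantification, heat-map generation and
#' cross-marker correlation, and the section-sampling simulation.  All
#' intermediates are written under \code{config$out_dir} and a JSON manifest
#' records parameters, seeds, per-stage metrics and output checksums; the
#' manifest is a pure function of inputs, configuration and seed (wall times
#' go to a separate JSON-lines log).
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly (also written to
#'   \code{out_dir/manifest.json}).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(out, "log.jsonl"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("histo3d")),
                   seed = config$seed,
                   parameters = list(pyramid_levels = config$pyramid_levels,
                                     ffd_grid = config$ffd_grid,
                                     heatmap_size_um = config$heatmap_size,
                                     sampling_steps = config$sampling_steps,
                                     n_components = config$n_components),
                   stages = list())
  outputs <- character(0)
  put <- function(path) { outputs <<- c(outputs, path); path }

  ds <- .stage("phantom", log_con, {
    if (!is.null(config$dataset)) config$dataset else make_phantom(config$phantom)
  })
  markers <- names(ds$markers)

  bfmask <- .stage("mask", log_con, {
    m <- auto_mask_blockface(ds$blockface, tissue = "dark")
    write_volume(ds$blockface, put(file.path(out, "blockface.nii.gz")))
    write_volume(m, put(file.path(out, "blockface_mask.nii.gz")))
    m
  })
  manifest$stages$mask <- list(tissue_voxels = sum(bfmask$data),
                               tissue_mm3 = mask_volume_mm3(bfmask))

  recon <- .stage("reconstruct", log_con, {
    res <- list()
    for (m in markers) {
      ser <- ds$markers[[m]]$series
      vol0 <- stack_sections(ser)
      d <- dim(vol0$data)
      data <- vol0$data
      ccs <- numeric(0)
      for (z in seq_len(d[3])) {
        if (!vol0$valid_planes[z]) next
        if (sum(bfmask$data[, , z]) < 50) next  # no tissue on this plane:
                                                # nothing to register against
        refp <- get_plane(ds$blockface, z - 1L)
        r <- register_section(refp, vol0$data[, , z, ],
                              pixel_size = unname(vol0$voxel_size[1]),
                              levels = config$pyramid_levels,
                              search_radius = config$search_radius,
                              max_iter = config$bm_max_iter)
        data[, , z, ] <- resample_image(vol0$data[, , z, ], r$transform,
                                        unname(vol0$voxel_size[1:2]),
                                        dim(refp)[1:2], background = 243)
        ccs <- c(ccs, r$report$metric_final)
      }
      v <- volume(data, unname(vol0$voxel_size), "histology",
                  valid_planes = vol0$valid_planes)
      write_volume(v, put(file.path(out, sprintf("recon_%s.nii.gz", m))))
      res[[m]] <- list(volume = v, mean_cc = mean(ccs), min_cc = min(ccs))
    }
    res
  })
  manifest$stages$reconstruct <- lapply(recon, function(r)
    list(mean_cc = r$mean_cc, min_cc = r$min_cc))

  seg <- .stage("segment", log_con, {
    res <- list()
    for (m in markers) {
      if (!is.null(config$model_paths[[m]])) {
        mp <- config$model_paths[[m]]
        if (!file.exists(mp))
          stop(sprintf("model file '%s' for marker %s not found", mp, m))
        model <- read_biovision(mp)
        f1_holdout <- NA_real_
      } else {
        pats <- phantom_patches(ds, m, n_patches = config$n_patches,
                                seed = config$seed + 17L)
        nh <- min(config$holdout_patches, length(pats) - 1L)
        hold <- if (nh > 0) pats[seq_len(nh)] else list()
        train <- pats[setdiff(seq_along(pats), seq_len(nh))]
        # augment with sub-pixel-shifted copies: the volume being classified
        # is a resampled reconstruction, so edge pixels are colour mixtures
        set.seed(config$seed + 29L)
        aug <- lapply(train, function(p) {
          sh <- runif(2, -0.35, 0.35) * unname(ds$blockface$voxel_size[1:2])
          img <- resample_image(p$image, affine2d(diag(2), sh),
                                unname(ds$blockface$voxel_size[1:2]),
                                background = 243)
          list(image = img, labels = p$labels)
        })
        model <- fit_biovision(c(train, aug),
                               n_components = config$n_components,
                               seed = config$seed)
        f1_holdout <- if (length(hold)) {
          pr <- unlist(lapply(hold, function(p) classify_image(p$image, model) == 1L))
          tr <- unlist(lapply(hold, function(p) p$labels == 1L))
          evaluate_f1(pr, tr)$f1
        } else NA_real_
      }
      write_biovision(model, put(file.path(out, sprintf("model_%s.json", m))))
      sv <- segment_volume(recon[[m]]$volume, model)
      write_volume(sv, put(file.path(out, sprintf("seg_%s.nii.gz", m))))
      res[[m]] <- list(mask = sv, f1_holdout = f1_holdout)
    }
    res
  })
  manifest$stages$segment <- lapply(seg, function(s)
    list(f1_holdout = s$f1_holdout, stained_voxels = sum(s$mask$data)))

  parc <- .stage("atlas", log_con, {
    p <- parcellate(ds$atlas$intensity, ds$atlas$labels,
                    apply_mask(ds$blockface, bfmask),
                    ffd_grid = config$ffd_grid,
                    coarsen = config$atlas_coarsen,
                    max_iter = config$ffd_max_iter)
    write_volume(p$labels, put(file.path(out, "labels.nii.gz")))
    write_transform(p$transform, put(file.path(out, "atlas_transform.json")))
    p
  })
  manifest$stages$atlas <- lapply(parc$reports, function(r)
    list(metric = r$metric_name, initial = r$metric_initial,
         final = r$metric_final, converged = r$converged))

  quant <- .stage("quantify", log_con, {
    res <- list()
    for (m in markers) {
      q <- ontology_quantify(seg[[m]]$mask, parc$labels, ds$ontology)
      write.csv(q, put(file.path(out, sprintf("loads_%s.csv", m))),
                row.names = FALSE)
      res[[m]] <- q
    }
    res
  })
  manifest$stages$quantify <- lapply(quant, function(q)
    list(root_load_pct = q$load_pct[q$depth == 0]))

  hms <- .stage("heatmap", log_con, {
    res <- list()
    for (m in markers) {
      hm <- occupancy_heatmap(seg[[m]]$mask, config$heatmap_size,
                              tissue_mask = bfmask)
      hm_s <- smooth_heatmap(hm)
      write_volume(hm_s, put(file.path(out, sprintf("heatmap_%s.nii.gz", m))))
      res[[m]] <- hm_s
    }
    res
  })
  cors <- .stage("correlate", log_con, {
    if (length(markers) < 2L) NULL else {
      pairs <- utils::combn(markers, 2, simplify = FALSE)
      df <- do.call(rbind, lapply(pairs, function(p) {
        ct <- correlate_heatmaps(hms[[p[1]]], hms[[p[2]]])
        data.frame(marker_a = p[1], marker_b = p[2], rho = ct$rho,
                   p_value = ct$p_value, n_voxels = ct$n_voxels)
      }))
      write.csv(df, put(file.path(out, "correlations.csv")), row.names = FALSE)
      df
    }
  })
  manifest$stages$correlate <- if (is.null(cors)) NULL else
    lapply(seq_len(nrow(cors)), function(i) as.list(cors[i, ]))

  samp <- .stage("sampling", log_con, {
    res <- list()
    leaf_labels <- function(name) {
      find <- function(node) {
        if (identical(node$name, name)) return(ontology_labels(node))
        for (k in node$children) { r <- find(k); if (!is.null(r)) return(r) }
        NULL
      }
      find(ds$ontology)
    }
    for (roi in config$sampling_rois) {
      labs <- leaf_labels(roi)
      for (m in markers) {
        s <- sampling_simulation(seg[[m]]$mask, parc$labels, labs,
                                 steps = config$sampling_steps)
        write.csv(s, put(file.path(out, sprintf("sampling_%s_%s.csv", roi, m))),
                  row.names = FALSE)
        res[[paste(roi, m, sep = ".")]] <- attr(s, "summary")
      }
    }
    res
  })
  manifest$stages$sampling <- lapply(samp, function(s)
    list(k = s$k, median_re = s$median_re))

  manifest$outputs <- as.list(tools::md5sum(sort(outputs)))
  names(manifest$outputs) <- basename(sort(outputs))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}
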