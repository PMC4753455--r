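#' Specification of the synthetic phantom study
#'
#' The default phantom mirrors a mouse-brain study design: 25 um coronal
#' sections with every 5th section stained (so reconstructed planes are
#' 125 um apart), a 128 x 96 x 60 voxel grid at 25 x 25 x 125 um, an
#' ellipsoidal "brain" with six labelled regions under a three-level
#' ontology, amyloid-plaque-like stain blobs (lognormal radii around 45 um)
#' whose density and rostro-caudal profile differ per region, a second
#' marker spatially colocalized with the first, per-section affine
#' distortions emulating sectioning/mounting deformations, and a known
#' affine + smooth elastic warp separating the atlas space from the
#' block-face space.
#'
#' @param dims grid dimensions (x, y, z).
#' @param voxel_size voxel edges in um.
#' @param seed RNG seed; the whole dataset is deterministic given the seed.
#' @param densities named list per marker: named numeric vector of per-region
#'   stain densities (volume fractions in 0..1).
#' @param profiles named list per marker: named character vector of
#'   rostro-caudal profiles per region (\code{"uniform"}, \code{"gradient"}
#'   or \code{"hotspot"}).
#' @param coloc named list per marker: name of an earlier marker whose blob
#'   centres seed this marker's blobs (spatial colocalization), or NULL.
#' @param coloc_prob probability that a colocalized marker's blob is seeded
#'   at a partner blob.
#' @param blob_meanlog,blob_sdlog,blob_range lognormal radius distribution
#'   (um) and clipping range.
#' @param rotation_deg,shear,translation_px,elastic_amp_px per-section
#'   distortion ranges (sampled uniformly in +/- range).
#' @param noise_sigma Gaussian pixel noise added to rendered sections.
#' @param atlas_rotation_deg,atlas_scale,atlas_shift_vox,atlas_elastic_amp_um
#'   parameters of the known atlas-to-block-face warp.
#' @return a \code{"phantom_spec"} list.
#' @export
phantom_spec <- function(dims = c(128, 96, 60), voxel_size = c(25, 25, 125),
                         seed = 0L,
                         densities = list(
                           abeta = c(cerebral_cortex = 0.05,
                                     white_matter = 0.005,
                                     striatum = 0.04,
                                     hippocampal_region = 0.05,
                                     thalamus = 0.03,
                                     other_brain = 0.01),
                           phago = c(cerebral_cortex = 0.03,
                                     white_matter = 0.003,
                                     striatum = 0.025,
                                     hippocampal_region = 0.03,
                                     thalamus = 0.02,
                                     other_brain = 0.006)),
                         profiles = list(
                           abeta = c(cerebral_cortex = "uniform",
                                     white_matter = "uniform",
                                     striatum = "uniform",
                                     hippocampal_region = "gradient",
                                     thalamus = "hotspot",
                                     other_brain = "uniform"),
                           phago = c(cerebral_cortex = "uniform",
                                     white_matter = "uniform",
                                     striatum = "uniform",
                                     hippocampal_region = "gradient",
                                     thalamus = "hotspot",
                                     other_brain = "uniform")),
                         coloc = list(abeta = NULL, phago = "abeta"),
                         coloc_prob = 0.8,
                         blob_meanlog = log(45), blob_sdlog = 0.35,
                         blob_range = c(20, 120),
                         rotation_deg = 4, shear = 0.03, translation_px = 10,
                         elastic_amp_px = 0, noise_sigma = 8,
                         atlas_rotation_deg = 3, atlas_scale = 1.04,
                         atlas_shift_vox = c(2, 1, 0.5),
                         atlas_elastic_amp_um = 60) {
  spec <- list(dims = as.integer(dims), voxel_size = as.numeric(voxel_size),
               seed = as.integer(seed), densities = densities,
               profiles = profiles, coloc = coloc, coloc_prob = coloc_prob,
               blob_meanlog = blob_meanlog, blob_sdlog = blob_sdlog,
               blob_range = blob_range, rotation_deg = rotation_deg,
               shear = shear, translation_px = translation_px,
               elastic_amp_px = elastic_amp_px, noise_sigma = noise_sigma,
               atlas_rotation_deg = atlas_rotation_deg,
               atlas_scale = atlas_scale,
               atlas_shift_vox = as.numeric(atlas_shift_vox),
               atlas_elastic_amp_um = atlas_elastic_amp_um)
  for (m in names(spec$densities))
    if (any(spec$densities[[m]] < 0 | spec$densities[[m]] > 1))
      .h3d_stop("h3d_spec_error", "densities must be in [0, 1]")
  if (any(c(rotation_deg, shear, translation_px, elastic_amp_px, noise_sigma) < 0))
    .h3d_stop("h3d_spec_error", "distortion/noise ranges must be non-negative")
  structure(spec, class = "phantom_spec")
}

# region table shared by geometry, ontology and manifest
.phantom_regions <- data.frame(
  label = 1:6,
  name = c("cerebral_cortex", "white_matter", "striatum",
           "hippocampal_region", "thalamus", "other_brain"),
  acronym = c("Cx", "WM", "Str", "HiR", "Thal", "Oth"),
  stringsAsFactors = FALSE)

.phantom_geometry <- function(dims, voxel_size) {
  ext <- dims * voxel_size
  xs <- ((seq_len(dims[1]) - 0.5) * voxel_size[1]) / ext[1]
  ys <- ((seq_len(dims[2]) - 0.5) * voxel_size[2]) / ext[2]
  zs <- ((seq_len(dims[3]) - 0.5) * voxel_size[3]) / ext[3]
  X <- array(rep(xs, times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep(ys, each = dims[1]), times = dims[3]), dims)
  Z <- array(rep(zs, each = dims[1] * dims[2]), dims)
  r <- sqrt(((X - 0.5) / 0.44)^2 + ((Y - 0.52) / 0.42)^2 + ((Z - 0.5) / 0.47)^2)
  lab <- array(0L, dims)
  inside <- r <= 1
  lab[inside] <- 6L                                   # other brain
  lab[inside & r > 0.60 & r <= 0.78] <- 2L            # white-matter shell
  lab[inside & r > 0.78] <- 1L                        # cortical shell
  blob <- function(cx, cy, cz, ax, ay, az)
    (((X - cx) / ax)^2 + ((Y - cy) / ay)^2 + ((Z - cz) / az)^2) <= 1
  deep <- inside & r <= 0.78
  str_l <- blob(0.34, 0.50, 0.30, 0.11, 0.14, 0.14)
  str_r <- blob(0.66, 0.50, 0.30, 0.11, 0.14, 0.14)
  hip_l <- blob(0.35, 0.42, 0.62, 0.10, 0.11, 0.13)
  hip_r <- blob(0.65, 0.42, 0.62, 0.10, 0.11, 0.13)
  tha <- blob(0.50, 0.56, 0.58, 0.13, 0.13, 0.12)
  lab[deep & (str_l | str_r)] <- 3L
  lab[deep & (hip_l | hip_r)] <- 4L
  lab[deep & tha & !(hip_l | hip_r)] <- 5L
  list(labels = lab, inside = inside, r = r, X = X, Y = Y, Z = Z)
}

.profile_factor <- function(profile, t) {
  switch(profile,
         uniform = rep(1, length(t)),
         gradient = 0.25 + 1.5 * t,
         hotspot = 0.12 + 3.2 * exp(-((t - 0.72) / 0.12)^2),
         .h3d_stop("h3d_spec_error", "unknown z profile '%s'", profile))
}

# stamp stain disks into one section until each region reaches its target
.stain_section <- function(lab2d, targets, spec, partner_centers = NULL) {
  d <- dim(lab2d)
  mask <- matrix(FALSE, d[1], d[2])
  centers <- list()
  px <- spec$voxel_size[1]
  for (l in seq_along(targets)) {
    tgt <- targets[l]
    if (is.na(tgt) || tgt <= 0) next
    idx <- which(lab2d == l)
    if (length(idx) == 0L) next
    n_target <- round(tgt * length(idx))
    if (n_target < 1L) next
    guard <- 0L
    while (sum(mask[idx]) < n_target && guard < 10L * n_target) {
      guard <- guard + 1L
      use_partner <- !is.null(partner_centers) && length(partner_centers) &&
        runif(1) < spec$coloc_prob
      if (use_partner) {
        c0 <- partner_centers[[sample.int(length(partner_centers), 1L)]]
        ci <- c0[1] + sample(-2:2, 1L); cj <- c0[2] + sample(-2:2, 1L)
        if (ci < 1 || cj < 1 || ci > d[1] || cj > d[2] || lab2d[ci, cj] != l) {
          p <- idx[sample.int(length(idx), 1L)]
          ci <- (p - 1L) %% d[1] + 1L; cj <- (p - 1L) %/% d[1] + 1L
        }
      } else {
        p <- idx[sample.int(length(idx), 1L)]
        ci <- (p - 1L) %% d[1] + 1L; cj <- (p - 1L) %/% d[1] + 1L
      }
      rad_um <- min(max(rlnorm(1, spec$blob_meanlog, spec$blob_sdlog),
                        spec$blob_range[1]), spec$blob_range[2])
      rad <- rad_um / px
      ri <- max(1L, floor(ci - rad)):min(d[1], ceiling(ci + rad))
      rj <- max(1L, floor(cj - rad)):min(d[2], ceiling(cj + rad))
      disk <- outer(ri - ci, rj - cj, function(a, b) a^2 + b^2 <= rad^2)
      sel <- disk & (lab2d[ri, rj] == l)
      mask[ri, rj][sel] <- TRUE
      centers[[length(centers) + 1L]] <- c(ci, cj)
    }
  }
  list(mask = mask, centers = centers)
}

.render_section <- function(lab2d, stain2d, sigma) {
  d <- dim(lab2d)
  img <- array(0, c(d, 3L))
  bgc <- c(243, 242, 240)
  tic <- c(231, 183, 193)
  stc <- c(112, 74, 44)
  # counterstain shading: anatomy is visible in real sections (white matter
  # pale, cell-dense structures darker), which is also what anchors the
  # section-to-block-face registration inside the tissue
  shade <- c(0.85, 1.08, 0.92, 0.96, 1.05, 1.0)
  tissue <- lab2d > 0L
  fac <- matrix(1, d[1], d[2])
  for (l in 1:6) fac[lab2d == l] <- shade[l]
  for (ch in 1:3) {
    m <- matrix(bgc[ch], d[1], d[2])
    m[tissue] <- (tic[ch] * fac)[tissue]
    m[stain2d] <- stc[ch]
    if (sigma > 0) m <- m + matrix(rnorm(length(m), 0, sigma), d[1], d[2])
    img[, , ch] <- pmin(pmax(m, 0), 255)
  }
  img
}

#' Apply a known distortion to one section
#'
#' Samples an affine distortion (rotation about the image centre, shear,
#' translation) within the spec's ranges, optionally adds a smooth sinusoidal
#' elastic field, and applies it identically to the image (linear
#' interpolation) and its ground-truth mask (nearest).  Returns the sampled
#' parameters and the pull-back transform that exactly undoes the
#' distortion, i.e. the transform a section-to-block-face registration
#' should recover.
#'
#' @param image RGB array (nx, ny, 3).
#' @param truth_mask logical/0-1 matrix, same in-plane dims.
#' @param spec a [phantom_spec()] (distortion ranges and voxel size).
#' @param seed RNG seed for the sampled parameters.
#' @return \code{list(image, mask, params, transform, elastic_amp_px)}:
#'   \code{transform} is the [affine2d()] mapping block-face world
#'   coordinates to distorted-section world coordinates.
#' @export
distort_section <- function(image, truth_mask, spec, seed = 0L) {
  set.seed(seed)
  px <- spec$voxel_size[1:2]
  d <- dim(image)[1:2]
  ctr <- d * px / 2
  th <- runif(1, -spec$rotation_deg, spec$rotation_deg) * pi / 180
  sh <- runif(1, -spec$shear, spec$shear)
  tr <- runif(2, -spec$translation_px, spec$translation_px) * px
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  S <- matrix(c(1, 0, sh, 1), 2, 2)
  M <- R %*% S
  fwd <- affine2d(M, ctr - as.numeric(M %*% ctr) + tr)
  inv <- invert_transform(fwd)
  img_d <- resample_image(image, inv, px, mode = "linear", background = 243)
  msk_d <- resample_image(matrix(as.numeric(truth_mask), d[1], d[2]), inv, px,
                          mode = "nearest", background = 0)
  if (spec$elastic_amp_px > 0) {
    # small sinusoidal in-plane warp applied after the affine
    amp <- spec$elastic_amp_px * px[1]
    ph <- runif(2, 0, 2 * pi)
    ext <- d * px
    warp <- function(p) cbind(p[, 1] + amp * sin(2 * pi * p[, 2] / ext[2] + ph[1]),
                              p[, 2] + amp * sin(2 * pi * p[, 1] / ext[1] + ph[2]))
    xs <- (seq_len(d[1]) - 0.5) * px[1]; ys <- (seq_len(d[2]) - 0.5) * px[2]
    pts <- warp(cbind(rep(xs, d[2]), rep(ys, each = d[1])))
    for (ch in 1:3)
      img_d[, , ch] <- matrix(.cpp_interp2(img_d[, , ch], pts, px, 0L, 1L, 0), d[1])
    msk_d <- matrix(.cpp_interp2(msk_d, pts, px, 1L, 0L, 0), d[1])
  }
  if (spec$noise_sigma > 0)
    for (ch in 1:3)
      img_d[, , ch] <- pmin(pmax(img_d[, , ch] +
        matrix(rnorm(prod(d), 0, spec$noise_sigma), d[1], d[2]), 0), 255)
  list(image = img_d, mask = msk_d,
       params = list(rotation_deg = th * 180 / pi, shear = sh,
                     translation_px = tr / px),
       transform = fwd,
       elastic_amp_px = spec$elastic_amp_px)
}

#' Generate the full synthetic phantom study
#'
#' Builds, deterministically from the spec's seed: the labelled ellipsoidal
#' brain; the block-face photographic volume (tissue darker than the bright
#' embedding background, with regional and smooth textural contrast); an
#' MRI-like atlas (intensity + labels) in a separate space related to the
#' block-face space by a known affine + smooth elastic warp; per-marker
#' ground-truth stain masks; rendered RGB histology sections, both pristine
#' and per-section distorted (with the true distortion transforms); and the
#' matching three-level ontology.
#'
#' @param spec a [phantom_spec()].
#' @return a \code{"phantom_dataset"} list: \code{blockface},
#'   \code{tissue_mask}, \code{labels} (all [volume()]s), \code{atlas}
#'   (\code{$intensity}, \code{$labels}, \code{$warp} = generative
#'   atlas-to-block-face map description), \code{ontology}, \code{markers}
#'   (per marker: \code{series} distorted [section_series()],
#'   \code{series_pristine}, \code{truth_mask} volume, \code{transforms}
#'   list of true per-section [affine2d()]s), \code{manifest}.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  dims <- spec$dims; vs <- spec$voxel_size
  geo <- .phantom_geometry(dims, vs)
  lab <- geo$labels
  labels_vol <- volume(lab, vs, "label")
  tissue <- volume(array(as.numeric(lab > 0L), dims), vs, "mask")

  # block-face: bright embedding background, darker structured tissue
  reg_off_bf <- c(-30, 14, -12, 6, 18, 0)
  bf <- array(242, dims)
  base <- 158 + 24 * (1 - geo$r) +
    8 * sin(6 * pi * geo$X) * cos(5 * pi * geo$Y) + 5 * sin(4 * pi * geo$Z)
  off <- array(0, dims)
  for (l in 1:6) off[lab == l] <- reg_off_bf[l]
  bf[lab > 0L] <- (base + off)[lab > 0L]
  bf <- bf + array(rnorm(prod(dims), 0, 2), dims)
  blockface <- volume(pmin(pmax(bf, 0), 255), vs, "blockface")

  # MRI-like contrast for the atlas: a different, nonlinearly spaced
  # intensity mapping that preserves the tissue-class ordering of the
  # block-face contrast, as anatomical modalities of the same brain do
  reg_int_mri <- c(95, 195, 130, 170, 215, 150)
  mri <- array(12, dims)
  mbase <- 14 * (1 - geo$r) + 7 * sin(5 * pi * geo$Y) * cos(4 * pi * geo$Z)
  for (l in 1:6) mri[lab == l] <- reg_int_mri[l]
  mri[lab > 0L] <- mri[lab > 0L] + mbase[lab > 0L]
  mri_vol <- volume(pmin(pmax(mri, 0), 255), vs, "mri")

  # atlas space: known generative warp G: atlas world -> block-face world
  ext <- dims * vs
  ctr <- ext / 2
  thz <- spec$atlas_rotation_deg * pi / 180
  A <- matrix(c(cos(thz), sin(thz), 0, -sin(thz), cos(thz), 0, 0, 0, 1), 3, 3) *
    spec$atlas_scale
  shift <- spec$atlas_shift_vox * vs
  G_aff <- affine3d(A, ctr - as.numeric(A %*% ctr) + shift)
  amp <- spec$atlas_elastic_amp_um
  G_fun <- function(p) {
    q <- apply_transform(G_aff, p)
    if (amp > 0)
      q <- q + cbind(amp * sin(2 * pi * p[, 3] / ext[3]),
                     amp * sin(2 * pi * p[, 1] / ext[1]),
                     0.5 * amp * sin(2 * pi * p[, 2] / ext[2]))
    q
  }
  pts <- voxel_centers(blockface)
  dst <- G_fun(pts)
  atlas_int <- volume(array(.cpp_interp3(as.numeric(mri_vol$data), dims, dst,
                                         vs, 0L, 0L, 12), dims), vs, "mri")
  atlas_lab <- volume(array(as.integer(round(
    .cpp_interp3(as.numeric(lab), dims, dst, vs, 1L, 0L, 0))), dims),
    vs, "label")

  ontology <- as_ontology(list(
    name = "brain", acronym = "Br", children = list(
      list(name = "telencephalon", acronym = "Tel", children = list(
        list(name = "cerebral_cortex", acronym = "Cx", labels = list(1L)),
        list(name = "white_matter", acronym = "WM", labels = list(2L)),
        list(name = "striatum", acronym = "Str", labels = list(3L)),
        list(name = "hippocampal_region", acronym = "HiR", labels = list(4L)))),
      list(name = "diencephalon", acronym = "Di", children = list(
        list(name = "thalamus", acronym = "Thal", labels = list(5L)))),
      list(name = "other_brain", acronym = "Oth", labels = list(6L)))))

  # region z spans for profile normalization
  zspan <- lapply(1:6, function(l) {
    zz <- which(apply(lab == l, 3, any))
    if (length(zz)) range(zz) else c(NA_integer_, NA_integer_)
  })

  markers <- list()
  blob_centers <- list()   # per marker: list over z of centre lists
  for (m in names(spec$densities)) {
    dens <- spec$densities[[m]]
    prof <- spec$profiles[[m]]
    truth <- array(0, dims)
    centers_z <- vector("list", dims[3])
    partner <- spec$coloc[[m]]
    for (z in seq_len(dims[3])) {
      lab2d <- lab[, , z]
      targets <- vapply(1:6, function(l) {
        nm <- .phantom_regions$name[l]
        dl <- if (nm %in% names(dens)) dens[[nm]] else 0
        if (dl <= 0 || is.na(zspan[[l]][1])) return(0)
        t <- if (diff(zspan[[l]]) > 0)
          (z - zspan[[l]][1]) / diff(zspan[[l]]) else 0.5
        if (z < zspan[[l]][1] || z > zspan[[l]][2]) return(0)
        dl * .profile_factor(prof[[nm]], t)
      }, numeric(1))
      st <- .stain_section(lab2d, targets, spec,
                           partner_centers = if (!is.null(partner))
                             blob_centers[[partner]][[z]] else NULL)
      truth[, , z] <- as.numeric(st$mask)
      centers_z[[z]] <- st$centers
    }
    blob_centers[[m]] <- centers_z
    truth_vol <- volume(truth, vs, "mask")
    imgs_p <- vector("list", dims[3])
    imgs_d <- vector("list", dims[3])
    trs <- vector("list", dims[3])
    for (z in seq_len(dims[3])) {
      img <- .render_section(lab[, , z], truth[, , z] > 0, spec$noise_sigma)
      imgs_p[[z]] <- img
      clean <- .render_section(lab[, , z], truth[, , z] > 0, 0)
      dz <- distort_section(clean, truth[, , z], spec,
                            seed = spec$seed + 1000L * match(m, names(spec$densities)) + z)
      imgs_d[[z]] <- dz$image
      trs[[z]] <- dz$transform
    }
    markers[[m]] <- list(
      series = section_series(imgs_d, seq_len(dims[3]) - 1L, vs[1], vs[3] / 5, 5L),
      series_pristine = section_series(imgs_p, seq_len(dims[3]) - 1L, vs[1], vs[3] / 5, 5L),
      truth_mask = truth_vol,
      transforms = trs)
  }

  manifest <- list(
    seed = spec$seed, dims = dims, voxel_size = vs,
    regions = .phantom_regions,
    atlas_warp = list(rotation_deg = spec$atlas_rotation_deg,
                      scale = spec$atlas_scale,
                      shift_vox = spec$atlas_shift_vox,
                      elastic_amp_um = spec$atlas_elastic_amp_um),
    markers = lapply(markers, function(mk)
      lapply(mk$transforms, function(t)
        list(matrix = t$matrix, translation = t$translation))))

  structure(list(spec = spec, blockface = blockface, tissue_mask = tissue,
                 labels = labels_vol, mri = mri_vol,
                 atlas = list(intensity = atlas_int, labels = atlas_lab,
                              warp = G_fun, warp_affine = G_aff),
                 ontology = ontology, markers = markers,
                 manifest = manifest),
            class = "phantom_dataset")
}

#' Expert-annotation patches sampled from the phantom
#'
#' Emulates the construction of a ground-truth set: small patches cut from
#' rendered sections, with every pixel labelled from the generating masks
#' (1 = stained, 2 = unstained tissue, 3 = background).
#'
#' @param phantom a [make_phantom()] dataset.
#' @param marker marker name (default first).
#' @param n_patches number of patches.
#' @param size patch edge in pixels.
#' @param seed RNG seed.
#' @return list of \code{list(image, labels)} patches usable by
#'   [fit_biovision()].
#' @export
phantom_patches <- function(phantom, marker = NULL, n_patches = 16L,
                            size = 24L, seed = 0L) {
  stopifnot(inherits(phantom, "phantom_dataset"))
  if (is.null(marker)) marker <- names(phantom$markers)[1]
  mk <- phantom$markers[[marker]]
  set.seed(seed)
  dims <- dim(phantom$labels$data)
  lab3 <- phantom$labels$data
  patches <- vector("list", n_patches)
  for (i in seq_len(n_patches)) {
    z <- sample.int(dims[3], 1L)
    img <- mk$series_pristine$images[[z]]
    x0 <- sample.int(dims[1] - size + 1L, 1L)
    y0 <- sample.int(dims[2] - size + 1L, 1L)
    sl <- list(x0:(x0 + size - 1L), y0:(y0 + size - 1L))
    pl <- matrix(3L, size, size)
    pl[lab3[sl[[1]], sl[[2]], z] > 0L] <- 2L
    pl[mk$truth_mask$data[sl[[1]], sl[[2]], z] > 0] <- 1L
    patches[[i]] <- list(image = img[sl[[1]], sl[[2]], , drop = FALSE],
                         labels = pl)
  }
  patches
}
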