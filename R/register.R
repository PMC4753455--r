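.report <- function(metric, initial, final, n_levels = 1L, converged = TRUE) {
  structure(list(metric_name = metric, metric_initial = initial,
                 metric_final = final, n_levels = as.integer(n_levels),
                 converged = isTRUE(converged)),
            class = "registration_report")
}

#' @export
print.registration_report <- function(x, ...) {
  cat(sprintf("<registration_report> %s: %.6g -> %.6g (%d level%s)%s\n",
              x$metric_name, x$metric_initial, x$metric_final, x$n_levels,
              if (x$n_levels > 1) "s" else "",
              if (x$converged) "" else "  [NOT converged]"))
  invisible(x)
}

.to_gray <- function(img) {
  if (length(dim(img)) == 3L) (img[, , 1] + img[, , 2] + img[, , 3]) / 3 else img
}

.downsample2 <- function(img) {
  d <- dim(img)
  d2 <- d %/% 2L * 2L
  img <- img[seq_len(d2[1]), seq_len(d2[2]), drop = FALSE]
  (img[seq(1, d2[1], 2), seq(1, d2[2], 2)] +
   img[seq(2, d2[1], 2), seq(1, d2[2], 2)] +
   img[seq(1, d2[1], 2), seq(2, d2[2], 2)] +
   img[seq(2, d2[1], 2), seq(2, d2[2], 2)]) / 4
}

.moments_init_2d <- function(ref, flo, psize, max_rot_deg = 20) {
  # principal-axes initialization: align tissue centroids and in-plane
  # orientation from image second moments (tissue = dark side of an Otsu
  # threshold in both modalities); makes the rotation component observable
  # before block matching refines
  feat <- function(img) {
    th <- tryCatch(otsu_threshold(img), h3d_degenerate_threshold = function(e) NULL)
    if (is.null(th)) return(NULL)
    m <- img <= th
    if (sum(m) < 25) return(NULL)
    idx <- which(m, arr.ind = TRUE)
    p <- sweep(idx - 0.5, 2, psize, "*")
    ctr <- colMeans(p)
    cc <- sweep(p, 2, ctr)
    mu <- crossprod(cc) / nrow(cc)
    ang <- 0.5 * atan2(2 * mu[1, 2], mu[1, 1] - mu[2, 2])
    ecc <- abs(mu[1, 1] - mu[2, 2]) / (mu[1, 1] + mu[2, 2])
    list(ctr = ctr, ang = ang, ecc = ecc)
  }
  a <- feat(ref); b <- feat(flo)
  if (is.null(a) || is.null(b)) return(NULL)
  dth <- b$ang - a$ang
  dth <- atan2(sin(dth), cos(dth))
  if (dth > pi / 2) dth <- dth - pi
  if (dth < -pi / 2) dth <- dth + pi
  # orientation is unreliable for near-circular sections
  if (min(a$ecc, b$ecc) < 0.05 || abs(dth) > max_rot_deg * pi / 180) dth <- 0
  R <- matrix(c(cos(dth), sin(dth), -sin(dth), cos(dth)), 2, 2)
  affine2d(R, b$ctr - as.numeric(R %*% a$ctr))
}

#' Register a stained section onto its block-face photograph
#'
#' Multi-resolution 2D affine registration by block matching: a
#' coarse-to-fine pyramid (default three resolution levels, each a factor-2
#' downsample) maximizes the correlation coefficient, correcting the
#' in-plane deformations introduced by sectioning, mounting and staining.
#' Transforms are estimated in world micrometres, so an estimate propagates
#' unchanged across pyramid levels.
#'
#' @param ref_photo block-face plane, matrix or RGB array (converted to
#'   luminance).
#' @param flo_section stained section image, matrix or RGB array.
#' @param pixel_size in-plane resolution (um/px) shared by both images.
#' @param levels pyramid levels (default 3).
#' @param block_size,search_radius,... passed to [block_matching()].
#' @return \code{list(transform, report)}: the [affine2d()] mapping
#'   block-face world coordinates to section world coordinates (pull-back:
#'   \code{resample_image(flo_section, transform, ...)} lands in block-face
#'   geometry), and a report with the correlation coefficient before/after.
#' @export
register_section <- function(ref_photo, flo_section, pixel_size = 1,
                             levels = 3L, block_size = 21L,
                             search_radius = 10L, ...) {
  ref <- .to_gray(ref_photo)
  flo <- .to_gray(flo_section)
  psize <- rep(as.numeric(pixel_size), length.out = 2)
  pyr_ref <- list(ref); pyr_flo <- list(flo); pyr_ps <- list(psize)
  for (l in seq_len(levels - 1L)) {
    pyr_ref[[l + 1L]] <- .downsample2(pyr_ref[[l]])
    pyr_flo[[l + 1L]] <- .downsample2(pyr_flo[[l]])
    pyr_ps[[l + 1L]] <- pyr_ps[[l]] * 2
  }
  cc0 <- suppressWarnings(tryCatch(correlation_coefficient(ref, flo),
                                   h3d_undefined_metric = function(e) NA_real_))
  t_cur <- .moments_init_2d(ref, flo, psize)
  for (l in rev(seq_len(levels))) {
    # shrink blocks at coarse levels so a grid of >= 10 blocks still fits;
    # shrink the search radius at fine levels, where only the residual of
    # the coarse estimate remains to be found
    bs <- min(block_size, max(5L, (min(dim(pyr_ref[[l]])) %/% 12L) * 2L + 1L))
    sr <- max(3L, as.integer(ceiling(search_radius / 2^(levels - l))))
    # translation-only at the coarsest level: its few blocks cannot
    # constrain a full affine and structured mismatches would corrupt it
    mdl <- if (l == levels && levels > 1L) "translation2d" else "affine2d"
    t_cur <- block_matching(pyr_ref[[l]], pyr_flo[[l]],
                            block_size = bs, step = max(2L, bs %/% 3L),
                            search_radius = sr,
                            model = mdl, pixel_size = pyr_ps[[l]],
                            init = t_cur, ...)
  }
  flo_w <- resample_image(flo, t_cur, psize, dim(ref)[1:2],
                          background = stats::median(flo))
  cc1 <- correlation_coefficient(ref, flo_w)
  list(transform = t_cur,
       report = .report("correlation_coefficient", cc0, cc1,
                        n_levels = levels,
                        converged = is.na(cc0) || cc1 >= cc0 - 1e-9))
}

.sample_points <- function(vol, mask = NULL, max_points = 30000L) {
  idx <- if (is.null(mask)) which(vol$data != 0) else which(mask > 0)
  if (length(idx) > max_points)
    idx <- idx[seq(1L, length(idx), length.out = max_points)]
  d <- dim(vol$data)[1:3]
  vs <- unname(vol$voxel_size)
  i0 <- idx - 1L
  cbind(((i0 %% d[1]) + 0.5) * vs[1],
        (((i0 %/% d[1]) %% d[2]) + 0.5) * vs[2],
        ((i0 %/% (d[1] * d[2])) + 0.5) * vs[3])
}

.mi_at <- function(pts, refbin, flo, A, tr, n_bins, flo_rng) {
  src <- sweep(pts %*% t(A), 2, tr, "+")
  v <- .cpp_interp3(as.numeric(flo$data), dim(flo$data)[1:3], src,
                    unname(flo$voxel_size), 0L, 1L, 0)
  bb <- .bin_values(v, n_bins, flo_rng)
  .mi_from_hist(matrix(tabulate(refbin + n_bins * (bb - 1L), n_bins * n_bins),
                       n_bins, n_bins))
}

#' Rigid 3D registration by mutual information
#'
#' Estimates the 6-parameter rigid transform (Euler angles about the
#' reference volume centre + translation) maximizing the mutual information
#' of the joint intensity histogram, using a derivative-free direction-set
#' optimizer (cyclic golden-section line searches over the six parameters),
#' suitable for multimodal pairs.
#'
#' @param ref,flo masked [volume()] objects with overlapping anatomy.
#' @param n_bins MI histogram bins (default 32).
#' @param rot_bracket,trans_bracket half-widths of the line-search intervals
#'   (degrees / um); the translation default is an eighth of the reference
#'   extent.
#' @param sweeps maximum direction-set sweeps.
#' @param max_points intensity samples used (subsampled deterministically).
#' @param init optional initial [rigid3d()].
#' @return \code{list(transform, report)}; on non-convergence the best
#'   transform so far is returned with \code{converged = FALSE}.
#' @export
register_rigid_3d <- function(ref, flo, n_bins = 32L, rot_bracket = 12,
                              trans_bracket = NULL, sweeps = 6L,
                              max_points = 30000L, init = NULL) {
  stopifnot(is_volume(ref), is_volume(flo))
  ctr <- volume_extent(ref) / 2
  if (is.null(trans_bracket)) trans_bracket <- max(volume_extent(ref)) / 8
  pts <- .sample_points(ref, max_points = max_points)
  refv <- .cpp_interp3(as.numeric(ref$data), dim(ref$data)[1:3], pts,
                       unname(ref$voxel_size), 1L, 1L, 0)
  refbin <- .bin_values(refv, n_bins, range(refv))
  flo_rng <- range(flo$data)
  par <- if (is.null(init)) {
    # initialize the translation by intensity centroid alignment
    com <- function(v) {
      p <- .sample_points(v, max_points = 1e5)
      w <- .cpp_interp3(as.numeric(v$data), dim(v$data)[1:3], p,
                        unname(v$voxel_size), 1L, 1L, 0)
      colSums(p * w) / sum(w)
    }
    c(0, 0, 0, com(flo) - com(ref))
  } else c(init$rotation, init$translation)
  f <- function(p) {
    t <- as_affine3d(rigid3d(p[1:3], p[4:6], center = ctr))
    .mi_at(pts, refbin, flo, t$matrix, t$translation, n_bins, flo_rng)
  }
  mi0 <- f(rep(0, 6))
  best <- f(par)
  brackets <- c(rep(rot_bracket, 3), rep(trans_bracket, 3))
  converged <- FALSE
  order6 <- c(4L, 5L, 6L, 1L, 2L, 3L)  # translations first
  for (s in seq_len(sweeps)) {
    prev <- best
    for (i in order6) {
      g <- function(x) { p <- par; p[i] <- x; -f(p) }
      o <- optimize(g, lower = par[i] - brackets[i],
                    upper = par[i] + brackets[i],
                    tol = if (i <= 3) 0.005 else 0.005 * mean(ref$voxel_size))
      if (-o$objective > best) { par[i] <- o$minimum; best <- -o$objective }
    }
    if (s > 1) brackets <- brackets / 2
    if (best - prev < 1e-4 * abs(best)) { converged <- TRUE; break }
  }
  list(transform = rigid3d(par[1:3], par[4:6], center = ctr),
       report = .report("mutual_information", mi0, best,
                        converged = converged))
}

#' Affine 3D registration by block matching
#'
#' Refines a rigid initialization into a full affine transform by 3D block
#' matching, maximizing the local correlation coefficient.
#'
#' @param ref,flo masked [volume()] objects.
#' @param init a [rigid3d()] or [affine3d()] initialization.
#' @param block_size,search_radius,... passed to [block_matching()].
#' @return \code{list(transform, report)} with correlation coefficient
#'   before/after on the reference support.
#' @export
register_affine_3d <- function(ref, flo, init = rigid3d(),
                               block_size = 7L, search_radius = 4L, ...) {
  stopifnot(is_volume(ref), is_volume(flo))
  msk <- ref$data != 0
  cc_of <- function(t) {
    w <- resample(flo, t, ref, mode = "linear")
    suppressWarnings(tryCatch(correlation_coefficient(ref$data, w$data, msk),
                              h3d_undefined_metric = function(e) NA_real_))
  }
  cc0 <- cc_of(init)
  t_fit <- block_matching(ref, flo, block_size = block_size,
                          search_radius = search_radius, model = "affine3d",
                          init = init, ...)
  cc1 <- cc_of(t_fit)
  list(transform = t_fit,
       report = .report("correlation_coefficient", cc0, cc1,
                        converged = is.na(cc0) || cc1 >= cc0 - 1e-9))
}

#' Elastic (free-form deformation) registration by mutual information
#'
#' Optimizes the displacements of a regular cubic B-spline control lattice
#' (default 10 x 10 x 10 points, i.e. 3000 parameters) by quasi-Newton
#' (L-BFGS) ascent of the mutual information, starting from an affine bulk
#' transform.  Gradients are finite differences computed by local joint-
#' histogram updates, exploiting the compact support of the spline basis.
#'
#' @param ref,flo masked [volume()] objects; \code{ref} must be at least as
#'   large as one lattice cell per axis.
#' @param init bulk [affine3d()] (or [rigid3d()]) applied before the elastic
#'   part; fixed during the elastic optimization.
#' @param grid_shape control points per axis (default \code{c(10, 10, 10)}).
#' @param n_bins MI histogram bins.
#' @param max_iter L-BFGS iteration cap.
#' @param max_points intensity samples used.
#' @param fd_step finite-difference step(s) in um; a vector runs one
#'   L-BFGS phase per step, warm-started (continuation).  The default,
#'   one smallest-voxel edge followed by a quarter, first captures
#'   voxel-scale deformation and then refines without the gradient noise a
#'   large step produces once the residual is sub-voxel.
#' @return \code{list(transform, report)}: an [ffd3d()] and the MI
#'   before/after; non-convergence is flagged, the best-so-far field
#'   returned.
#' @export
register_ffd <- function(ref, flo, init = affine3d(),
                         grid_shape = c(10, 10, 10), n_bins = 32L,
                         max_iter = 40L, max_points = 60000L,
                         fd_step = NULL) {
  stopifnot(is_volume(ref), is_volume(flo))
  if (inherits(init, "rigid3d")) init <- as_affine3d(init)
  ext <- volume_extent(ref)
  if (any(dim(ref$data)[1:3] < 4L))
    .h3d_stop("h3d_value_error", "reference volume smaller than the control lattice")
  if (is.null(fd_step)) fd_step <- min(ref$voxel_size) * c(1, 0.25)
  pts <- .sample_points(ref, max_points = max_points)
  refv <- .cpp_interp3(as.numeric(ref$data), dim(ref$data)[1:3], pts,
                       unname(ref$voxel_size), 1L, 1L, 0)
  refbin <- .bin_values(refv, n_bins, range(refv)) - 1L  # 0-based for C++
  flo_rng <- range(flo$data)
  gdim <- as.integer(grid_shape)
  npar <- prod(gdim) * 3L
  cache <- new.env(parent = emptyenv())
  run_cpp <- function(par, eps, want_grad)
    .cpp_ffd_mi_grad(refbin, pts, init$matrix, init$translation,
                     par, gdim, ext,
                     as.numeric(flo$data), dim(flo$data)[1:3],
                     unname(flo$voxel_size), as.integer(n_bins),
                     flo_rng[1], flo_rng[2], eps, want_grad)
  evalfg <- function(par, want_grad) {
    if (!is.null(cache$par) && identical(cache$par, par) && !want_grad)
      return(list(mi = cache$mi))
    r <- run_cpp(par, 1, want_grad)
    cache$par <- par; cache$mi <- r$mi
    r
  }
  evalfg2 <- function(par, eps) {
    r <- run_cpp(par, eps, TRUE)
    cache$par <- par; cache$mi <- r$mi
    r
  }
  mi0 <- evalfg(rep(0, npar), FALSE)$mi
  par <- rep(0, npar)
  iters <- diff(round(seq(0, max_iter, length.out = length(fd_step) + 1L)))
  for (ph in seq_along(fd_step)) {
    eps_cur <- fd_step[ph]
    o <- optim(par,
               fn = function(p) -evalfg(p, FALSE)$mi,
               gr = function(p) -as.numeric(evalfg2(p, eps_cur)$grad),
               method = "L-BFGS-B",
               control = list(maxit = iters[ph], factr = 1e10))
    par <- o$par
  }
  grid <- array(par, c(gdim, 3L))
  list(transform = ffd3d(grid, ext, bulk = init),
       report = .report("mutual_information", mi0, -o$value,
                        converged = o$convergence %in% c(0L, 1L)))
}
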