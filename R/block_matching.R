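#' @section Robust transform fitting:
#' The correspondence set produced by the block search is contaminated by
#' mismatches in flat or ambiguous blocks; the transform is therefore fitted
#' by trimmed least squares: fit, rank residuals, keep the best fraction,
#' refit, for a few rounds.
#' @noRd
.fit_affine_nd <- function(P, Q) {
  # Q ~ P %*% t(A) + t  via lm on homogeneous coordinates
  n <- ncol(P)
  X <- cbind(P, 1)
  beta <- solve(crossprod(X), crossprod(X, Q))  # (n+1) x n
  A <- t(beta[seq_len(n), , drop = FALSE])
  tr <- as.numeric(beta[n + 1L, ])
  if (n == 2L) affine2d(A, tr) else affine3d(A, tr)
}

.euler_from_matrix <- function(M) {
  b <- asin(pmin(pmax(-M[3, 1], -1), 1))
  a <- atan2(M[2, 1], M[1, 1])
  c <- atan2(M[3, 2], M[3, 3])
  c(a, b, c) * 180 / pi
}

.fit_rigid3d <- function(P, Q) {
  pb <- colMeans(P); qb <- colMeans(Q)
  H <- crossprod(sweep(P, 2, pb), sweep(Q, 2, qb))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid3d(.euler_from_matrix(R), qb - as.numeric(R %*% pb))
}

.fit_translation2d <- function(P, Q) {
  d <- Q - P
  affine2d(diag(2), c(median(d[, 1]), median(d[, 2])))
}

.robust_fit <- function(P, Q, model, trim = 0.5, rounds = 3L) {
  fitfun <- switch(model,
                   affine2d = .fit_affine_nd, affine3d = .fit_affine_nd,
                   translation2d = .fit_translation2d,
                   rigid3d = .fit_rigid3d)
  keep <- seq_len(nrow(P))
  fit <- NULL
  for (r in seq_len(rounds)) {
    fit <- fitfun(P[keep, , drop = FALSE], Q[keep, , drop = FALSE])
    res <- sqrt(rowSums((apply_transform(fit, P) - Q)^2))
    nk <- max(ceiling(trim * nrow(P)), ncol(P) + 2L)
    keep <- order(res)[seq_len(min(nk, nrow(P)))]
  }
  fit
}

#' Block-matching transform estimation
#'
#' Partitions the reference into blocks, finds for each block with
#' sufficient intensity variance the displacement in the floating image that
#' maximizes the local correlation coefficient (exhaustive integer search
#' plus parabolic sub-pixel refinement), then fits the requested transform
#' model to the correspondence set by trimmed least squares.  The
#' match-and-fit cycle iterates, warping the floating image through the
#' current estimate, until the incremental update is below \code{tol}.
#'
#' @param ref,flo 2D images (matrices) for \code{model = "affine2d"}, or
#'   [volume()] objects for the 3D models.
#' @param block_size odd block edge length in pixels/voxels.
#' @param search_radius maximum displacement searched, in pixels/voxels.
#' @param model \code{"affine2d"}, \code{"translation2d"} (2D, robust
#'   median displacement; used at the coarsest pyramid level where the
#'   correspondence geometry cannot constrain a full affine),
#'   \code{"rigid3d"} or \code{"affine3d"}.
#' @param pixel_size in-plane resolution of the 2D images (um/px); ignored
#'   for volumes.
#' @param step block spacing (default half the block size, i.e. 50% overlap).
#' @param min_var variance floor for including a block; defaults to
#'   \code{(2\% of the reference intensity range)^2}.
#' @param trim fraction of correspondences kept by the robust fit.
#' @param cc_min minimum block correlation for a correspondence to enter the
#'   fit (ambiguous matches in flat or noise-only blocks are discarded; if
#'   fewer than 10 matches survive, the 10 best are kept).
#' @param max_iter,tol iteration control; \code{tol} is the maximum corner
#'   displacement (pixels/voxels) of the incremental update.
#' @param init optional initial transform (pull-back convention).
#' @return the fitted transform (class per \code{model}).
#' @export
block_matching <- function(ref, flo, block_size = 21L, search_radius = 10L,
                           model = c("affine2d", "translation2d", "rigid3d",
                                     "affine3d"),
                           pixel_size = c(1, 1), step = NULL, min_var = NULL,
                           trim = 0.5, cc_min = 0.3, max_iter = 10L, tol = 0.05,
                           init = NULL) {
  model <- match.arg(model)
  half <- as.integer(block_size) %/% 2L
  keep_confident <- function(m) {
    ok <- m[, "cc"] >= cc_min
    if (sum(ok) >= 10L) m[ok, , drop = FALSE]
    else m[order(m[, "cc"], decreasing = TRUE)[seq_len(min(10L, nrow(m)))], ,
           drop = FALSE]
  }
  if (is.null(step)) step <- max(half, 1L)
  if (model %in% c("affine2d", "translation2d")) {
    stopifnot(is.matrix(ref), is.matrix(flo))
    psize <- rep(as.numeric(pixel_size), length.out = 2)
    if (is.null(min_var)) min_var <- (0.02 * diff(range(ref)))^2
    t_cur <- if (is.null(init)) affine2d() else init
    for (it in seq_len(max_iter)) {
      flo_w <- resample_image(flo, t_cur, psize, dim(ref)[1:2],
                              background = stats::median(flo))
      m <- .cpp_block_match_2d(ref, flo_w, half, as.integer(step),
                               as.integer(search_radius), min_var)
      if (nrow(m) < 10L)
        .h3d_stop("h3d_insufficient_data",
                  "only %d valid blocks (>= 10 required)", nrow(m))
      m <- keep_confident(m)
      P <- sweep(m[, 1:2, drop = FALSE] + 0.5, 2, psize, "*")
      Q <- P + sweep(m[, 3:4, drop = FALSE], 2, psize, "*")
      t_d <- .robust_fit(P, Q, model, trim = trim)
      t_cur <- compose_transforms(t_cur, t_d)
      corners <- cbind(c(0, dim(ref)[1], 0, dim(ref)[1]) * psize[1],
                       c(0, 0, dim(ref)[2], dim(ref)[2]) * psize[2])
      upd <- max(sqrt(rowSums((apply_transform(t_d, corners) - corners)^2))) /
        mean(psize)
      if (upd < tol) break
    }
    return(t_cur)
  }
  # 3D models
  stopifnot(is_volume(ref), is_volume(flo))
  vs <- unname(ref$voxel_size)
  if (is.null(min_var)) min_var <- (0.02 * diff(range(ref$data)))^2
  t_cur <- if (is.null(init)) affine3d() else {
    if (inherits(init, "rigid3d")) as_affine3d(init) else init
  }
  d <- dim(ref$data)[1:3]
  for (it in seq_len(max_iter)) {
    flo_w <- resample(flo, t_cur, ref, mode = "linear",
                      background = stats::median(flo$data))
    m <- .cpp_block_match_3d(as.numeric(ref$data), d,
                             as.numeric(flo_w$data), d,
                             half, as.integer(step),
                             as.integer(search_radius), min_var)
    if (nrow(m) < 10L)
      .h3d_stop("h3d_insufficient_data",
                "only %d valid blocks (>= 10 required)", nrow(m))
    m <- keep_confident(m)
    P <- sweep(m[, 1:3, drop = FALSE] + 0.5, 2, vs, "*")
    Q <- P + sweep(m[, 4:6, drop = FALSE], 2, vs, "*")
    t_d <- .robust_fit(P, Q, if (model == "rigid3d") "rigid3d" else "affine3d",
                       trim = trim)
    t_cur <- compose_transforms(t_cur, t_d)
    ext <- d * vs
    corners <- as.matrix(expand.grid(c(0, ext[1]), c(0, ext[2]), c(0, ext[3])))
    upd <- max(sqrt(rowSums((apply_transform(t_d, corners) - corners)^2))) /
      mean(vs)
    if (upd < tol) break
  }
  if (model == "rigid3d") {
    # re-express the composed affine as the nearest rigid transform
    sv <- svd(t_cur$matrix)
    R <- sv$u %*% t(sv$v)
    if (det(R) < 0) R <- sv$u %*% diag(c(1, 1, -1)) %*% t(sv$v)
    return(rigid3d(.euler_from_matrix(R), t_cur$translation))
  }
  t_cur
}
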