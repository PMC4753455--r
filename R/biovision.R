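#' Per-pixel colour + local-intensity features
#'
#' Each pixel of an RGB section image yields a 4-D feature vector
#' \code{(R, G, B, local_intensity)}.  Local intensity is the mean luminance
#' (per-pixel mean of R, G, B) over the pixel and its 4-connected in-plane
#' neighbours (a 5-pixel cross; set \code{include_center = FALSE} for the
#' strict 4-neighbour mean).  Image borders are handled by edge replication.
#' The local term makes the classifier robust to pixel noise in
#' neuropathology images.
#'
#' @param image \code{(nx, ny, 3)} RGB array, intensities 0-255.
#' @param include_center include the centre pixel in the local mean
#'   (default TRUE).
#' @return \code{(nx, ny, 4)} feature array.
#' @export
extract_features <- function(image, include_center = TRUE) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L)
    .h3d_stop("h3d_channel_error", "extract_features expects an RGB image")
  lum <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  nx <- d[1]; ny <- d[2]
  shift <- function(m, dx, dy) {
    xi <- pmin(pmax(seq_len(nx) + dx, 1L), nx)
    yi <- pmin(pmax(seq_len(ny) + dy, 1L), ny)
    m[xi, yi, drop = FALSE]
  }
  acc <- shift(lum, -1L, 0L) + shift(lum, 1L, 0L) +
         shift(lum, 0L, -1L) + shift(lum, 0L, 1L)
  local <- if (include_center) (acc + lum) / 5 else acc / 4
  out <- array(0, c(nx, ny, 4L))
  out[, , 1:3] <- image
  out[, , 4] <- local
  out
}

# ---- Gaussian mixture via EM ------------------------------------------------

.log_gauss <- function(X, mean, chol_cov) {
  # log N(x; mean, Sigma) with Sigma = t(chol) %*% chol
  d <- ncol(X)
  ctr <- sweep(X, 2, mean)
  z <- backsolve(chol_cov, t(ctr), transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(chol_cov))) - 0.5 * d * log(2 * pi)
}

.gmm_fit <- function(X, k, seed = 0L, reg = 1e-3, max_iter = 200L,
                     tol = 1e-6) {
  n <- nrow(X); d <- ncol(X)
  set.seed(seed)
  km <- suppressWarnings(kmeans(X, centers = min(k, n), nstart = 5L,
                                iter.max = 50L))
  means <- km$centers
  if (nrow(means) < k)
    means <- means[rep_len(seq_len(nrow(means)), k), , drop = FALSE]
  covs <- lapply(seq_len(k), function(j) {
    idx <- which(km$cluster == ((j - 1L) %% nrow(km$centers)) + 1L)
    S <- if (length(idx) > d) cov(X[idx, , drop = FALSE]) else diag(d)
    S[!is.finite(S)] <- 0
    S + diag(reg, d)
  })
  w <- rep(1 / k, k)
  loglik <- numeric(0)
  resp <- matrix(0, n, k)
  for (it in seq_len(max_iter)) {
    for (j in seq_len(k))
      resp[, j] <- log(w[j]) + .log_gauss(X, means[j, ], chol(covs[[j]]))
    m <- apply(resp, 1, max)
    lse <- m + log(rowSums(exp(resp - m)))
    loglik <- c(loglik, sum(lse))
    if (it > 1 && loglik[it] - loglik[it - 1L] < tol * abs(loglik[it - 1L]) &&
        loglik[it] >= loglik[it - 1L]) break
    r <- exp(resp - lse)
    nk <- colSums(r)
    w <- nk / n
    for (j in seq_len(k)) {
      if (nk[j] < 1e-8) next
      means[j, ] <- colSums(X * r[, j]) / nk[j]
      ctr <- sweep(X, 2, means[j, ])
      covs[[j]] <- crossprod(ctr * sqrt(r[, j])) / nk[j] + diag(reg, d)
    }
  }
  list(weights = w, means = means, covariances = covs, loglik = loglik)
}

.gmm_logdens <- function(X, gmm) {
  k <- length(gmm$weights)
  lp <- vapply(seq_len(k), function(j)
    log(gmm$weights[j]) + .log_gauss(X, gmm$means[j, ], chol(gmm$covariances[[j]])),
    numeric(nrow(X)))
  lp <- matrix(lp, nrow = nrow(X))
  m <- apply(lp, 1, max)
  m + log(rowSums(exp(lp - m)))
}

#' Supervised stain-classification model
#'
#' Fits, for each of the three classes (positively stained tissue,
#' non-stained tissue, background), a multivariate Gaussian mixture over the
#' 4-D colour + local-intensity feature space of the expert-labelled pixels,
#' by EM with k-means initialization.  Classification then assigns each
#' pixel by Bayes rule (class priors times mixture density).
#'
#' @param truth a list of patches, each \code{list(image = RGB array,
#'   labels = integer matrix)} with label codes 0 = unlabeled, 1 = stained,
#'   2 = unstained, 3 = background.
#' @param n_components mixture components per class (default 3), scalar or
#'   length 3.
#' @param seed RNG seed for the k-means initialization (recorded in the
#'   model).
#' @param priors \code{"proportions"} (labelled-pixel class proportions,
#'   default) or \code{"uniform"}.
#' @param reg diagonal covariance regularization.
#' @param include_center passed to [extract_features()].
#' @return an object of class \code{"biovision_model"}; \code{$loglik} holds
#'   the per-class EM log-likelihood traces (non-decreasing).
#' @export
fit_biovision <- function(truth, n_components = 3L, seed = 0L,
                          priors = c("proportions", "uniform"), reg = 1e-3,
                          include_center = TRUE) {
  priors <- match.arg(priors)
  classes <- c("stained", "unstained", "background")
  n_components <- rep_len(as.integer(n_components), 3L)
  if (any(n_components < 1L))
    .h3d_stop("h3d_value_error", "n_components must be >= 1 for every class")
  feats <- vector("list", 3L)
  for (p in truth) {
    if (!any(p$labels > 0L))
      .h3d_stop("h3d_value_error", "a training patch contains no labelled pixel")
    if (any(p$labels < 0L | p$labels > 3L))
      .h3d_stop("h3d_value_error", "label codes must be in 0..3")
    fe <- extract_features(p$image, include_center = include_center)
    fm <- matrix(fe, ncol = 4L)
    for (cl in 1:3) {
      idx <- which(as.integer(p$labels) == cl)
      if (length(idx)) feats[[cl]] <- rbind(feats[[cl]], fm[idx, , drop = FALSE])
    }
  }
  counts <- vapply(feats, function(f) if (is.null(f)) 0L else nrow(f), integer(1))
  short <- counts < 10L * n_components
  if (any(short))
    .h3d_stop("h3d_training_error",
              "too few labelled pixels for class %s (need >= 10 per component)",
              paste(classes[short], collapse = ", "))
  fits <- lapply(1:3, function(cl)
    .gmm_fit(feats[[cl]], n_components[cl], seed = seed + cl))
  pri <- if (priors == "uniform") rep(1 / 3, 3) else counts / sum(counts)
  structure(list(classes = classes,
                 mixtures = setNames(fits, classes),
                 priors = setNames(pri, classes),
                 n_components = setNames(n_components, classes),
                 loglik = setNames(lapply(fits, `[[`, "loglik"), classes),
                 seed = as.integer(seed),
                 config = list(priors = priors, reg = reg,
                               include_center = include_center)),
            class = "biovision_model")
}

#' @export
print.biovision_model <- function(x, ...) {
  cat(sprintf("<biovision_model> classes %s; components %s; priors %s\n",
              paste(x$classes, collapse = "/"),
              paste(x$n_components, collapse = "/"),
              paste(signif(x$priors, 3), collapse = "/")))
  invisible(x)
}

#' Classify an RGB section image
#'
#' Bayes rule over the fitted class mixtures: each pixel gets the class
#' maximizing prior times mixture density at its feature vector.  Exact
#' posterior ties are broken by class order (stained < unstained <
#' background).
#'
#' @param image \code{(nx, ny, 3)} RGB array.
#' @param model a [fit_biovision()] model.
#' @return integer label matrix (1 = stained, 2 = unstained, 3 = background).
#' @export
classify_image <- function(image, model) {
  stopifnot(inherits(model, "biovision_model"))
  fe <- extract_features(image, include_center = model$config$include_center)
  X <- matrix(fe, ncol = 4L)
  post <- vapply(1:3, function(cl)
    log(model$priors[cl]) + .gmm_logdens(X, model$mixtures[[cl]]),
    numeric(nrow(X)))
  post <- matrix(post, nrow = nrow(X))
  if (any(!is.finite(post) & !(post == -Inf)))
    .h3d_stop("h3d_numeric_error", "non-finite class density (degenerate covariance?)")
  lab <- max.col(post, ties.method = "first")
  matrix(as.integer(lab), dim(image)[1], dim(image)[2])
}

#' Segment the stained class across a histology volume
#'
#' Classification runs per section in 2D (the features are in-plane), then
#' the stained-class masks are stacked back into a volume.  Invalid
#' (missing-section) planes stay empty and keep their invalid flag.
#'
#' @param vol RGB histology [volume()].
#' @param model a [fit_biovision()] model.
#' @return a mask [volume()] of the stained class.
#' @export
segment_volume <- function(vol, model) {
  stopifnot(is_volume(vol))
  d <- dim(vol$data)
  if (length(d) != 4L)
    .h3d_stop("h3d_channel_error", "segment_volume expects an RGB histology volume")
  out <- array(0, d[1:3])
  for (z in seq_len(d[3])) {
    if (!vol$valid_planes[z]) next
    lab <- classify_image(vol$data[, , z, ], model)
    out[, , z] <- as.numeric(lab == 1L)
  }
  volume(out, unname(vol$voxel_size), "mask", valid_planes = vol$valid_planes)
}

#' Precision, recall and F1 of a binary segmentation
#'
#' Voxel-wise counts of true/false positives and false negatives give
#' precision \code{P = TP / (TP + FP)} (proportion of true positives among
#' voxels classified positive), recall \code{R = TP / (TP + FN)} (proportion
#' of ground-truth positives recovered) and \code{F1 = 2PR / (P + R)}.  By
#' declared convention each ratio is 0 when its denominator is 0, hence
#' \code{F1 = 0} when \code{P + R = 0}.
#'
#' @param pred,truth binary masks (arrays or mask [volume()]s) of identical
#'   shape.
#' @return \code{list(precision, recall, f1, tp, fp, fn)}.
#' @export
evaluate_f1 <- function(pred, truth) {
  pred <- if (is_volume(pred)) pred$data else pred
  truth <- if (is_volume(truth)) truth$data else truth
  if (!identical(dim(pred), dim(truth)))
    .h3d_stop("h3d_shape_error", "prediction and truth have different shapes")
  p <- pred > 0; t <- truth > 0
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t)
  P <- if (tp + fp > 0) tp / (tp + fp) else 0
  R <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  list(precision = P, recall = R, f1 = f1, tp = tp, fp = fp, fn = fn)
}

#' Serialize a BioVision model to JSON
#' @param model a [fit_biovision()] model.
#' @param path file path; \code{NULL} returns the JSON string.
#' @export
write_biovision <- function(model, path = NULL) {
  rec <- list(classes = model$classes,
              priors = as.numeric(model$priors),
              n_components = as.integer(model$n_components),
              seed = model$seed, config = model$config,
              mixtures = lapply(model$mixtures, function(m)
                list(weights = m$weights, means = m$means,
                     covariances = m$covariances, loglik = m$loglik)))
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' Read a BioVision model written by [write_biovision()]
#' @param path file path or JSON string.
#' @export
read_biovision <- function(path) {
  rec <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  classes <- as.character(unlist(rec$classes))
  mix <- lapply(rec$mixtures, function(m)
    list(weights = as.numeric(unlist(m$weights)),
         means = do.call(rbind, lapply(m$means, function(r) as.numeric(unlist(r)))),
         covariances = lapply(m$covariances, function(S)
           do.call(rbind, lapply(S, function(r) as.numeric(unlist(r))))),
         loglik = as.numeric(unlist(m$loglik))))
  structure(list(classes = classes, mixtures = setNames(mix, classes),
                 priors = setNames(as.numeric(unlist(rec$priors)), classes),
                 n_components = setNames(as.integer(unlist(rec$n_components)), classes),
                 loglik = setNames(lapply(mix, `[[`, "loglik"), classes),
                 seed = rec$seed,
                 config = lapply(rec$config, function(x) x)),
            class = "biovision_model")
}
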