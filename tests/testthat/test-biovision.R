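test_that("features of a constant image are (R, G, B, luminance) everywhere", {
  img <- array(0, c(6, 5, 3))
  img[, , 1] <- 60; img[, , 2] <- 120; img[, , 3] <- 180
  fe <- extract_features(img)
  expect_equal(unique(as.numeric(fe[, , 1])), 60)
  expect_equal(unique(as.numeric(fe[, , 4])), 120)  # (60+120+180)/3
  expect_error(extract_features(matrix(1, 5, 5)), class = "h3d_channel_error")
})

test_that("local intensity is the centre-inclusive 5-pixel cross mean", {
  img <- array(50, c(5, 5, 3))   # luminance 50 everywhere
  img[3, 3, ] <- 100             # centre pixel luminance 100
  fe <- extract_features(img)
  expect_equal(fe[3, 3, 4], (100 + 4 * 50) / 5)  # = 60
  # centre-exclusive convention for comparison
  fe4 <- extract_features(img, include_center = FALSE)
  expect_equal(fe4[3, 3, 4], 50)
  # corner of a uniform image equals the interior (edge replication)
  u <- array(80, c(4, 4, 3))
  fu <- extract_features(u)
  expect_equal(fu[1, 1, 4], fu[2, 2, 4])
})

make_cluster_patch <- function(n, mean_rgb, sd, label, seed) {
  set.seed(seed)
  side <- ceiling(sqrt(n))
  img <- array(0, c(side, side, 3))
  for (ch in 1:3)
    img[, , ch] <- pmin(pmax(matrix(rnorm(side^2, mean_rgb[ch], sd), side), 0), 255)
  list(image = img, labels = matrix(label, side, side))
}

test_that("a point-mass class yields the regularization-floor covariance", {
  img <- array(0, c(8, 8, 3))
  img[, , 1] <- 60; img[, , 2] <- 120; img[, , 3] <- 180
  pat <- list(list(image = img, labels = matrix(1L, 8, 8)),
              make_cluster_patch(64, c(200, 150, 150), 4, 2L, 1),
              make_cluster_patch(64, c(240, 240, 240), 4, 3L, 2))
  m <- fit_biovision(pat, n_components = 1L)
  st <- m$mixtures$stained
  expect_equal(as.numeric(st$means[1, ]), c(60, 120, 180, 120), tolerance = 1e-6)
  expect_equal(diag(st$covariances[[1]]), rep(1e-3, 4), tolerance = 1e-9)
})

test_that("EM recovers two well-separated component means within 2 units", {
  p1 <- make_cluster_patch(200, c(60, 40, 30), 1.5, 1L, 3)
  p2 <- make_cluster_patch(200, c(140, 110, 90), 1.5, 1L, 4)
  tiss <- make_cluster_patch(200, c(230, 180, 190), 2, 2L, 5)
  bg <- make_cluster_patch(200, c(245, 245, 245), 2, 3L, 6)
  m <- fit_biovision(list(p1, p2, tiss, bg), n_components = c(2L, 1L, 1L),
                     seed = 0)
  mu <- m$mixtures$stained$means[order(m$mixtures$stained$means[, 1]), ]
  expect_lt(max(abs(mu[1, 1:3] - c(60, 40, 30))), 2)
  expect_lt(max(abs(mu[2, 1:3] - c(140, 110, 90))), 2)
})

test_that("training errors: zero components, missing classes, bad label codes", {
  p <- make_cluster_patch(100, c(100, 100, 100), 2, 1L, 7)
  expect_error(fit_biovision(list(p), n_components = 0L),
               class = "h3d_value_error")
  expect_error(fit_biovision(list(p), n_components = 1L),
               class = "h3d_training_error")  # unstained/background absent
  bad <- p; bad$labels[1, 1] <- 9L
  expect_error(fit_biovision(list(bad), n_components = 1L),
               class = "h3d_value_error")
})

test_that("EM log-likelihood is non-decreasing at every iteration", {
  ph <- small_phantom()
  pats <- phantom_patches(ph, "abeta", n_patches = 10, seed = 2)
  m <- fit_biovision(pats, n_components = 3L, seed = 0)
  for (cl in names(m$loglik)) {
    ll <- m$loglik[[cl]]
    expect_gte(length(ll), 2)
    expect_true(all(diff(ll) >= -1e-6 * pmax(abs(ll[-length(ll)]), 1)))
  }
})

test_that("classification is Bayes argmax with declared tie-breaking", {
  tr <- list(make_cluster_patch(120, c(60, 40, 30), 2, 1L, 8),
             make_cluster_patch(120, c(230, 180, 190), 2, 2L, 9),
             make_cluster_patch(120, c(245, 245, 245), 2, 3L, 10))
  m <- fit_biovision(tr, n_components = 1L, priors = "uniform")
  # pixel exactly at the stained mean -> stained
  img <- array(0, c(3, 3, 3))
  img[, , 1] <- 60; img[, , 2] <- 40; img[, , 3] <- 30
  expect_true(all(classify_image(img, m) == 1L))
  # exactly equal posteriors across two classes -> first class in order wins
  m2 <- m
  m2$mixtures$unstained <- m2$mixtures$stained
  m2$priors <- setNames(rep(1 / 3, 3), m$classes)
  expect_true(all(classify_image(img, m2) == 1L))
})

test_that("scaling all priors by a constant leaves classifications unchanged", {
  ph <- small_phantom()
  pats <- phantom_patches(ph, "abeta", n_patches = 10, seed = 3)
  m <- fit_biovision(pats, n_components = 2L, seed = 0)
  img <- ph$markers$abeta$series_pristine$images[[8]]
  l1 <- classify_image(img, m)
  m$priors <- m$priors * 7.3
  expect_identical(classify_image(img, m), l1)
})

test_that("F1 formula: exact hand-computed cases and conventions", {
  expect_equal(evaluate_f1(c(1, 1, 0), c(1, 1, 0))$f1, 1.0)
  # TP = 2, FP = 1, FN = 1 -> P = R = 2/3, F1 = 2/3
  r <- evaluate_f1(c(1, 1, 1, 0), c(1, 1, 0, 1))
  expect_equal(r$precision, 2 / 3)
  expect_equal(r$recall, 2 / 3)
  expect_equal(r$f1, 2 / 3)
  expect_equal(evaluate_f1(c(0, 0), c(1, 0))$f1, 0)  # empty prediction
  expect_error(evaluate_f1(matrix(0, 2, 2), matrix(0, 3, 3)),
               class = "h3d_shape_error")
})

test_that("segmentation F1 approaches 1 as rendering noise vanishes", {
  f1_at_sigma <- function(sigma) {
    ph <- make_phantom(small_phantom_spec(noise_sigma = sigma))
    pats <- phantom_patches(ph, "abeta", n_patches = 12, seed = 4)
    m <- fit_biovision(pats, n_components = 2L, seed = 0)
    zs <- c(8L, 10L, 12L)
    pr <- unlist(lapply(zs, function(z)
      classify_image(ph$markers$abeta$series_pristine$images[[z]], m) == 1L))
    tr <- unlist(lapply(zs, function(z)
      ph$markers$abeta$truth_mask$data[, , z] > 0))
    evaluate_f1(pr, tr)$f1
  }
  f1s <- vapply(c(16, 8, 4, 0), f1_at_sigma, numeric(1))
  expect_true(all(diff(f1s) >= -1e-3))   # monotone toward sigma = 0
  expect_gte(f1s[length(f1s)], 0.99)
  expect_gte(f1s[2], 0.95)               # sigma = 8 already >= 0.95
})

test_that("our mixture density agrees with mclust on the same parameters", {
  skip_if_not_installed("mclust")
  set.seed(13)
  X <- rbind(matrix(rnorm(400, 0, 1), ncol = 4),
             matrix(rnorm(400, 5, 1), ncol = 4))
  fit <- histo3d:::.gmm_fit(X, 2L, seed = 1, reg = 1e-6)
  ours <- histo3d:::.gmm_logdens(X, fit)
  dens <- sapply(1:2, function(j)
    mclust::dmvnorm(X, fit$means[j, ], fit$covariances[[j]]))
  ref <- log(as.numeric(dens %*% fit$weights))
  expect_equal(ours, ref, tolerance = 1e-8)
})

test_that("models survive a JSON round trip and classify identically", {
  ph <- small_phantom()
  pats <- phantom_patches(ph, "abeta", n_patches = 10, seed = 5)
  m <- fit_biovision(pats, n_components = 2L, seed = 0)
  p <- withr::local_tempfile(fileext = ".json")
  write_biovision(m, p)
  m2 <- read_biovision(p)
  img <- ph$markers$abeta$series_pristine$images[[10]]
  expect_identical(classify_image(img, m2), classify_image(img, m))
})
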