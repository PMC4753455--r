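test_that("affine transforms compose and invert in closed form", {
  a <- affine2d(matrix(c(1.1, 0.1, -0.05, 0.95), 2, 2), c(10, -5))
  pts <- matrix(runif(20, 0, 100), ncol = 2)
  back <- apply_transform(invert_transform(a), apply_transform(a, pts))
  expect_equal(back, pts, tolerance = 1e-9)

  b <- affine2d(diag(2) * 2, c(1, 1))
  ab <- compose_transforms(a, b)
  expect_equal(apply_transform(ab, pts),
               apply_transform(a, apply_transform(b, pts)), tolerance = 1e-9)

  expect_error(affine2d(matrix(0, 2, 2)), class = "h3d_singular_transform")
  expect_error(affine3d(matrix(0, 3, 3)), class = "h3d_singular_transform")
})

test_that("rigid composition with its inverse is identity to 1e-6", {
  r <- rigid3d(c(20, -10, 5), c(100, -50, 30), center = c(500, 400, 300))
  pts <- matrix(runif(30, 0, 1000), ncol = 3)
  back <- apply_transform(invert_transform(r), apply_transform(r, pts))
  expect_lt(max(abs(back - pts)), 1e-6)
  # Euler angles survive a matrix round trip
  M <- as_affine3d(r)$matrix
  expect_equal(histo3d:::.euler_from_matrix(M), c(20, -10, 5), tolerance = 1e-9)
})

test_that("a zero FFD control grid reduces to its bulk affine", {
  bulk <- affine3d(diag(3) * 1.05, c(10, 20, 30))
  f <- ffd3d(array(0, c(10, 10, 10, 3)), extent = c(1000, 1000, 1000),
             bulk = bulk)
  pts <- matrix(runif(30, 0, 1000), ncol = 3)
  expect_equal(apply_transform(f, pts), apply_transform(bulk, pts),
               tolerance = 1e-9)
  expect_error(invert_transform(f), class = "h3d_value_error")
})

test_that("the B-spline displacement field is continuous and interpolating-smooth", {
  set.seed(1)
  grid <- array(rnorm(10 * 10 * 10 * 3, 0, 50), c(10, 10, 10, 3))
  f <- ffd3d(grid, extent = c(1000, 800, 600))
  p <- matrix(c(500, 400, 300), 1, 3)
  eps <- 1e-3
  d0 <- apply_transform(f, p)
  for (ax in 1:3) {
    p2 <- p; p2[ax] <- p2[ax] + eps
    expect_lt(max(abs(apply_transform(f, p2) - d0)), 1)  # ~Lipschitz bound
  }
})

test_that("transforms serialize to JSON and back without loss", {
  tdir <- withr::local_tempdir()
  trs <- list(affine2d(matrix(c(1, 0.2, -0.1, 1), 2, 2), c(3, 4)),
              rigid3d(c(5, -3, 1), c(10, 20, 30), center = c(1, 2, 3)),
              affine3d(diag(3) * 1.1, c(-5, 0, 5)),
              ffd3d(array(seq_len(4^3 * 3), c(4, 4, 4, 3)), c(100, 100, 100),
                    bulk = affine3d(diag(3), c(1, 1, 1))))
  for (t in trs) {
    p <- file.path(tdir, "t.json")
    write_transform(t, p)
    expect_equal(class(read_transform(p))[1], class(t)[1])
  }
  # numeric fidelity on a 3D affine
  t <- affine3d(matrix(rnorm(9) + diag(3), 3, 3), rnorm(3))
  t2 <- read_transform(write_transform(t))
  expect_equal(t2$matrix, t$matrix, tolerance = 1e-12)
  expect_equal(t2$translation, t$translation, tolerance = 1e-12)
  # FFD grid fidelity
  f <- ffd3d(array(rnorm(4^3 * 3), c(4, 4, 4, 3)), c(10, 20, 30))
  f2 <- read_transform(write_transform(f))
  expect_equal(f2$control_grid, f$control_grid, tolerance = 1e-12)
  expect_equal(f2$extent, f$extent)
})

test_that("resampling through the identity returns the input bit-exactly (nearest)", {
  v <- volume(array(sample(0:9, 4 * 3 * 2, TRUE), c(4, 3, 2)), c(10, 10, 10), "label")
  out <- resample(v, affine3d(), v, mode = "nearest")
  expect_identical(out$data, v$data)
})

test_that("integer-voxel translation in nearest mode shifts the grid exactly", {
  arr <- array(seq_len(5 * 4 * 3), c(5, 4, 3))
  v <- volume(arr, c(10, 10, 10), "mri")
  # pull-back by +1 voxel in x: output voxel i reads input voxel i+1
  out <- resample(v, affine3d(diag(3), c(10, 0, 0)), v, mode = "nearest",
                  background = -1)
  expect_equal(out$data[1:4, , ], arr[2:5, , ])
  expect_true(all(out$data[5, , ] == -1))
})

test_that("label resampling through an FFD never creates new labels", {
  ph <- small_phantom()
  set.seed(2)
  grid <- array(rnorm(10^3 * 3, 0, 40), c(10, 10, 10, 3))
  f <- ffd3d(grid, volume_extent(ph$labels))
  out <- resample(ph$labels, f, ph$labels, mode = "nearest")
  expect_true(all(unique(as.integer(out$data)) %in%
                    unique(as.integer(ph$labels$data))))
})

test_that("resample composition matches composed-transform resampling", {
  # fully smooth volume: no mask edge, so double interpolation stays within
  # a couple of gray levels of single interpolation
  d <- c(32, 28, 24)
  xs <- (seq_len(d[1]) - 0.5) / d[1]; ys <- (seq_len(d[2]) - 0.5) / d[2]
  zs <- (seq_len(d[3]) - 0.5) / d[3]
  X <- array(rep(xs, d[2] * d[3]), d)
  Y <- array(rep(rep(ys, each = d[1]), d[3]), d)
  Z <- array(rep(zs, each = d[1] * d[2]), d)
  v <- volume(120 + 50 * sin(4 * pi * X) * cos(3 * pi * Y) + 40 * sin(3 * pi * Z),
              c(100, 100, 100), "mri")
  t1 <- affine3d(diag(3), c(150, -100, 50))
  t2 <- as_affine3d(rigid3d(c(4, 0, 0), c(0, 0, 0),
                            center = volume_extent(v) / 2))
  two_step <- resample(resample(v, t1), t2)
  one_step <- resample(v, compose_transforms(t1, t2))
  inner <- two_step$data[5:28, 5:24, 5:20]   # away from background edges
  expect_lt(max(abs(inner - one_step$data[5:28, 5:24, 5:20])), 2)
})
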