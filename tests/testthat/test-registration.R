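# Known-transform recovery on synthetic data is the primary acceptance
# surface of the registration stack.

corner_error <- function(t_est, t_true, nx, ny) {
  corners <- cbind(c(0, nx, 0, nx), c(0, 0, ny, ny))
  mean(sqrt(rowSums((apply_transform(t_est, corners) -
                       apply_transform(t_true, corners))^2)))
}

test_that("block matching returns the identity for identical images", {
  img <- textured_image(100, 90)
  t <- block_matching(img, img, model = "affine2d")
  expect_lt(max(abs(t$matrix - diag(2))), 0.01)
  expect_lt(max(abs(t$translation)), 0.1)
})

test_that("block matching recovers a pure translation within 0.5 px", {
  img <- textured_image(100, 90)
  shift <- affine2d(diag(2), c(7, -4))
  flo <- resample_image(img, invert_transform(shift), 1, background = median(img))
  t <- block_matching(img, flo, model = "affine2d")
  expect_lt(max(abs(t$translation - c(7, -4))), 0.5)
})

test_that("block matching recovers rotation + translation to < 1 px corner error", {
  img <- textured_image(120, 100)
  th <- 8 * pi / 180; ctr <- c(60, 50)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  t_true <- affine2d(R, ctr - as.numeric(R %*% ctr) + c(5, 3))
  flo <- resample_image(img, invert_transform(t_true), 1, background = median(img))
  t <- block_matching(img, flo, model = "affine2d")
  expect_lt(corner_error(t, t_true, 120, 100), 1)
})

test_that("block matching fails cleanly without enough valid blocks", {
  flat <- matrix(5, 60, 60)
  expect_error(block_matching(flat, flat, model = "affine2d"),
               class = "h3d_insufficient_data")
})

test_that("section registration recovers a histology-like distortion to < 1 px", {
  img <- textured_image(128, 96)
  th <- 4 * pi / 180; sh <- 0.05; ctr <- c(64, 48)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  S <- matrix(c(1, 0, sh, 1), 2, 2)
  M <- R %*% S
  t_true <- affine2d(M, ctr - as.numeric(M %*% ctr) + c(12, -7))
  flo <- resample_image(img, invert_transform(t_true), 1, background = median(img))
  r <- register_section(img, flo, pixel_size = 1, levels = 3)
  expect_equal(r$report$n_levels, 3L)
  expect_lt(corner_error(r$transform, t_true, 128, 96), 1)
  expect_gte(r$report$metric_final, r$report$metric_initial - 1e-9)
})

test_that("registering an image to itself leaves CC at essentially 1", {
  img <- textured_image(96, 80)
  r <- register_section(img, img, pixel_size = 1)
  expect_gte(r$report$metric_final, 0.999)
})

test_that("phantom section distortions are recovered from the ground truth", {
  ph <- small_phantom()
  z <- 10L
  mk <- ph$markers$abeta
  ref <- get_plane(ph$blockface, z)
  flo <- mk$series$images[[z + 1L]]
  r <- register_section(ref, flo, pixel_size = unname(ph$blockface$voxel_size[1]))
  d <- dim(ref)
  px <- unname(ph$blockface$voxel_size[1])
  err <- corner_error(r$transform, mk$transforms[[z + 1L]],
                      d[1] * px, d[2] * px) / px
  expect_lt(err, 1)
})

test_that("rigid 3D registration recovers a known motion within 0.5 deg / 0.5 voxel", {
  ref <- textured_volume()
  t_true <- rigid3d(c(5, 0, 0), c(500, 300, 200), center = volume_extent(ref) / 2)
  flo <- resample(ref, invert_transform(t_true), ref, mode = "linear")
  r <- register_rigid_3d(ref, flo)
  expect_lt(max(abs(r$transform$rotation - c(5, 0, 0))), 0.5)
  expect_lt(max(abs(r$transform$translation - c(500, 300, 200))), 50)  # 0.5 voxel
  expect_gte(r$report$metric_final, r$report$metric_initial - 1e-9)
})

test_that("rigid registration of a volume to itself stays at the identity", {
  ref <- textured_volume(c(36, 32, 24))
  r <- register_rigid_3d(ref, ref)
  expect_lt(max(abs(r$transform$rotation)), 0.1)
  expect_lt(max(abs(r$transform$translation)), 10)  # 0.1 voxel
})

test_that("MI-based rigid registration tolerates an intensity remap (gamma 0.5)", {
  ref <- textured_volume()
  t_true <- rigid3d(c(5, 0, 0), c(500, 300, 200), center = volume_extent(ref) / 2)
  flo <- resample(ref, invert_transform(t_true), ref, mode = "linear")
  flo$data <- 255 * (pmax(flo$data, 0) / 255)^0.5
  r <- register_rigid_3d(ref, flo)
  expect_lt(max(abs(r$transform$rotation - c(5, 0, 0))), 1)
  expect_lt(max(abs(r$transform$translation - c(500, 300, 200))), 100)  # 1 voxel
})

test_that("affine 3D registration recovers isotropic and anisotropic scaling within 1%", {
  ref <- textured_volume()
  ctr <- volume_extent(ref) / 2
  for (sc in list(c(1.1, 1.1, 1.1), c(1.05, 0.95, 1.0))) {
    A <- diag(sc)
    t_true <- affine3d(A, ctr - as.numeric(A %*% ctr))
    flo <- resample(ref, invert_transform(t_true), ref, mode = "linear")
    r <- register_affine_3d(ref, flo, init = rigid3d())
    expect_lt(max(abs(diag(r$transform$matrix) - sc) / sc), 0.01)
    expect_gte(r$report$metric_final, r$report$metric_initial - 1e-9)
  }
})

test_that("affine registration started at the exact answer stays there", {
  ref <- textured_volume(c(36, 32, 24))
  ctr <- volume_extent(ref) / 2
  A <- diag(3) * 1.08
  t_true <- affine3d(A, ctr - as.numeric(A %*% ctr))
  flo <- resample(ref, invert_transform(t_true), ref, mode = "linear")
  r <- register_affine_3d(ref, flo, init = t_true)
  expect_lt(max(abs(r$transform$matrix - t_true$matrix)), 0.02)
  expect_lt(max(abs(r$transform$translation - t_true$translation)), 50)
})

test_that("FFD defaults to a 10 x 10 x 10 control lattice", {
  f <- ffd3d(extent = c(100, 100, 100))
  expect_identical(dim(f$control_grid), c(10L, 10L, 10L, 3L))
})

test_that("FFD registration of a volume to itself keeps the field near zero", {
  ref <- textured_volume(c(36, 32, 24))
  r <- register_ffd(ref, ref, max_iter = 10)
  maxdisp <- max(abs(r$transform$control_grid))
  expect_lt(maxdisp, 50)  # < 0.5 voxel
})

test_that("FFD registration recovers >= 80% of a smooth sinusoidal warp", {
  ref <- textured_volume()
  ext <- volume_extent(ref)
  warp <- function(p)
    cbind(p[, 1] + 400 * sin(2 * pi * p[, 3] / ext[3]) * sin(pi * p[, 2] / ext[2]),
          p[, 2] + 400 * cos(2 * pi * p[, 1] / ext[1]) * sin(pi * p[, 3] / ext[3]),
          p[, 3] + 300 * sin(2 * pi * p[, 2] / ext[2]))
  warped <- warp_volume(ref, warp)
  r <- register_ffd(warped, ref, max_iter = 60)
  pts <- histo3d:::.sample_points(warped, max_points = 20000)
  true_dst <- warp(pts)
  est_dst <- apply_transform(r$transform, pts)
  res0 <- mean(sqrt(rowSums((pts - true_dst)^2)))
  res1 <- mean(sqrt(rowSums((est_dst - true_dst)^2)))
  expect_gte(1 - res1 / res0, 0.80)
  expect_gte(r$report$metric_final, r$report$metric_initial - 1e-9)
})
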