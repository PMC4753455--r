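test_that("the same seed reproduces the dataset bit-identically", {
  s <- small_phantom_spec(seed = 9L)
  a <- make_phantom(s)
  b <- make_phantom(s)
  expect_identical(a$blockface$data, b$blockface$data)
  expect_identical(a$labels$data, b$labels$data)
  expect_identical(a$markers$abeta$truth_mask$data, b$markers$abeta$truth_mask$data)
  expect_identical(a$markers$abeta$series$images[[5]],
                   b$markers$abeta$series$images[[5]])
  expect_identical(a$atlas$labels$data, b$atlas$labels$data)
})

test_that("zero density everywhere yields empty truth masks and 0% loads", {
  dens <- list(abeta = c(cerebral_cortex = 0, white_matter = 0, striatum = 0,
                         hippocampal_region = 0, thalamus = 0, other_brain = 0))
  prof <- list(abeta = c(cerebral_cortex = "uniform", white_matter = "uniform",
                         striatum = "uniform", hippocampal_region = "uniform",
                         thalamus = "uniform", other_brain = "uniform"))
  ph <- make_phantom(small_phantom_spec(densities = dens, profiles = prof,
                                        coloc = list(abeta = NULL)))
  expect_equal(sum(ph$markers$abeta$truth_mask$data), 0)
  expect_equal(region_load(ph$markers$abeta$truth_mask, ph$labels, 1:6)$load_pct, 0)
})

test_that("density 1 in one region saturates that region's true load", {
  dens <- list(abeta = c(cerebral_cortex = 0, white_matter = 0, striatum = 0,
                         hippocampal_region = 0, thalamus = 1, other_brain = 0))
  prof <- list(abeta = c(cerebral_cortex = "uniform", white_matter = "uniform",
                         striatum = "uniform", hippocampal_region = "uniform",
                         thalamus = "uniform", other_brain = "uniform"))
  ph <- make_phantom(small_phantom_spec(densities = dens, profiles = prof,
                                        coloc = list(abeta = NULL)))
  expect_equal(region_load(ph$markers$abeta$truth_mask, ph$labels, 5L)$load_pct,
               100)
  expect_equal(region_load(ph$markers$abeta$truth_mask, ph$labels, 1L)$load_pct, 0)
})

test_that("invalid densities and negative ranges are rejected", {
  expect_error(phantom_spec(densities = list(a = c(cerebral_cortex = 1.5))),
               class = "h3d_spec_error")
  expect_error(phantom_spec(rotation_deg = -1), class = "h3d_spec_error")
})

test_that("distort_section bookkeeping returns exactly the applied parameters", {
  spec <- small_phantom_spec(noise_sigma = 0)
  base <- outer(seq_len(40), seq_len(30), function(i, j)
    120 + 60 * sin(i / 4) * cos(j / 3))
  img <- array(rep(base, 3), c(40, 30, 3))
  msk <- matrix(rbinom(40 * 30, 1, 0.1), 40, 30)
  d0 <- distort_section(img, msk, spec, seed = 4)
  # the returned transform maps reference coords to distorted coords:
  # pulling the distorted image back through it must undo the distortion
  und <- resample_image(d0$image, d0$transform, spec$voxel_size[1:2],
                        background = 243)
  inner <- und[8:33, 8:23, ]
  expect_lt(mean(abs(inner - img[8:33, 8:23, ])), 5)  # interpolation losses only
  expect_lte(abs(d0$params$rotation_deg), spec$rotation_deg)
  expect_lte(abs(d0$params$shear), spec$shear)
  # zero-range spec leaves the image untouched with an identity transform
  spec0 <- small_phantom_spec(rotation_deg = 0, shear = 0, translation_px = 0,
                              noise_sigma = 0)
  dz <- distort_section(img, msk, spec0, seed = 1)
  expect_equal(dz$image, img, tolerance = 1e-9)
  expect_equal(dz$transform$matrix, diag(2))
  expect_equal(dz$transform$translation, c(0, 0), tolerance = 1e-9)
})

test_that("small affine distortions approximately preserve the mask area", {
  spec <- small_phantom_spec(noise_sigma = 0, translation_px = 3)
  msk <- matrix(0, 60, 50)
  msk[20:40, 15:35] <- 1
  img <- array(100, c(60, 50, 3))
  d <- distort_section(img, msk, spec, seed = 6)
  expect_lt(abs(sum(d$mask) - sum(msk)) / sum(msk), 0.02)
})

test_that("ground-truth regional loads match the blob-stamping targets to first order", {
  ph <- small_phantom()
  # cortex target 5% uniform; stamping overshoots by at most one blob per pass
  rl <- region_load(ph$markers$abeta$truth_mask, ph$labels, 1L)
  expect_gt(rl$load_pct, 4)
  expect_lt(rl$load_pct, 8)
  # the hotspot region concentrates caudally: caudal half > rostral half
  pr <- rostrocaudal_profile(ph$markers$abeta$truth_mask, ph$labels, 5L)
  n <- length(pr$load_pct)
  expect_gt(mean(pr$load_pct[(n %/% 2 + 1):n]), mean(pr$load_pct[1:(n %/% 2)]))
})

test_that("colocalized markers correlate spatially in the ground truth", {
  ph <- small_phantom()
  h1 <- occupancy_heatmap(ph$markers$abeta$truth_mask, 125,
                          tissue_mask = ph$tissue_mask)
  h2 <- occupancy_heatmap(ph$markers$phago$truth_mask, 125,
                          tissue_mask = ph$tissue_mask)
  r <- correlate_heatmaps(h1, h2)
  expect_gt(r$rho, 0.1)
  expect_lt(r$p_value, 1e-3)
})

test_that("training patches carry all three classes with plausible proportions", {
  ph <- small_phantom()
  pats <- phantom_patches(ph, "abeta", n_patches = 16, seed = 1)
  labs <- unlist(lapply(pats, function(p) p$labels))
  expect_setequal(sort(unique(labs)), 1:3)
  expect_gt(sum(labs == 1L), 30)   # enough stained pixels to fit a mixture
})
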