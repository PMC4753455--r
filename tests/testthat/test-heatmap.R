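test_that("full and half-stained blocks aggregate to exact occupancy fractions", {
  st <- array(0, c(10, 10, 2))
  st[1:5, 1:5, 1] <- 1                    # one 5x5 block fully stained
  st[6:10, 1:5, 1][, 1:2] <- 0
  st[6:10, 1:3, 1] <- 1                   # neighbouring block 15/25 stained
  seg <- volume(st, c(25, 25, 125), "mask")
  hm <- occupancy_heatmap(seg, 125)
  expect_equal(dim(hm$data), c(2L, 2L, 2L))
  expect_equal(hm$data[1, 1, 1], 1.0)
  expect_equal(hm$data[2, 1, 1], 15 / 25)
  expect_equal(hm$data[1, 1, 2], 0)
  expect_false(hm$smoothed)
})

test_that("a non-integer aggregation ratio is rejected with a suggestion", {
  seg <- volume(array(0, c(10, 10, 2)), c(30, 30, 125), "mask")
  err <- tryCatch(occupancy_heatmap(seg, 125), condition = identity)
  expect_s3_class(err, "h3d_resolution_error")
  expect_match(conditionMessage(err), "150")
})

test_that("pre-smoothing conservation is integer-exact", {
  ph <- small_phantom()
  seg <- ph$markers$abeta$truth_mask
  hm <- occupancy_heatmap(seg, 125, tissue_mask = ph$tissue_mask)
  lhs <- sum(hm$data * hm$covered_counts)
  expect_equal(lhs, sum(seg$data), tolerance = 1e-9)
  # global heat-map load equals whole-brain occupancy of the covered voxels
  expect_equal(sum(hm$stained_counts) / sum(hm$covered_counts),
               mean(seg$data), tolerance = 1e-12)
})

test_that("aggregation is monotone under adding stained voxels", {
  set.seed(21)
  st <- array(rbinom(10 * 10 * 2, 1, 0.2), c(10, 10, 2))
  seg1 <- volume(st, c(25, 25, 125), "mask")
  st2 <- st; st2[st2 == 0][1:20] <- 1
  seg2 <- volume(st2, c(25, 25, 125), "mask")
  h1 <- occupancy_heatmap(seg1, 125)
  h2 <- occupancy_heatmap(seg2, 125)
  expect_true(all(h2$data >= h1$data - 1e-12))
})

test_that("invalid planes drop out of the aggregation denominator", {
  st <- array(0, c(5, 5, 3))
  st[, , 1] <- 1; st[, , 2] <- 1          # plane 2 stained but invalid
  seg <- volume(st, c(25, 25, 125), "mask",
                valid_planes = c(TRUE, FALSE, TRUE))
  hm <- occupancy_heatmap(seg, 125)
  expect_equal(as.numeric(hm$data), c(1, 0, 0))
  expect_equal(hm$valid_planes, c(TRUE, FALSE, TRUE))
})

test_that("smoothing keeps a constant heat map unchanged inside the mask", {
  st <- array(0, c(20, 20, 4))
  seg <- volume(st, c(25, 25, 125), "mask")
  hm <- occupancy_heatmap(seg, 125)
  hm$data[] <- 0.37
  sm <- smooth_heatmap(hm)
  expect_lt(max(abs(sm$data - 0.37)), 1e-12)
  expect_true(sm$smoothed)
  expect_error(smooth_heatmap(sm), class = "h3d_value_error")
})

test_that("an impulse keeps its mass inside the mask after normalized smoothing", {
  st <- array(0, c(40, 40, 8))
  seg <- volume(st, c(25, 25, 125), "mask")
  hm <- occupancy_heatmap(seg, 125)        # 8 x 8 x 8 grid
  hm$data[4, 4, 4] <- 0.8
  sm <- smooth_heatmap(hm)
  # mask normalization re-weights near the grid boundary, so the total is
  # preserved approximately, not exactly
  expect_equal(sum(sm$data), 0.8, tolerance = 0.05)
  expect_lt(max(sm$data), 0.8)             # spread out, not amplified
})

test_that("masked mean is preserved within 0.5% by normalized smoothing", {
  ph <- full_phantom()   # study-scale rim fraction
  hm <- occupancy_heatmap(ph$markers$abeta$truth_mask, 125,
                          tissue_mask = ph$tissue_mask)
  sm <- smooth_heatmap(hm)
  m <- hm$brain_mask > 0
  expect_lt(abs(mean(sm$data[m]) - mean(hm$data[m])) / mean(hm$data[m]), 0.005)
})

test_that("sigma/FWHM kernel conventions differ as documented", {
  st <- array(0, c(40, 40, 8))
  seg <- volume(st, c(25, 25, 125), "mask")
  hm <- occupancy_heatmap(seg, 125)
  hm$data[4, 4, 4] <- 1
  s1 <- smooth_heatmap(hm, kernel = "sigma")
  s2 <- smooth_heatmap(hm, kernel = "fwhm")
  expect_gt(s2$data[4, 4, 4], s1$data[4, 4, 4])  # narrower kernel, taller peak
})

test_that("Spearman correlation of heat maps matches hand-ranked oracles", {
  mkhm <- function(vals) {
    v <- volume(array(vals, c(length(vals), 1, 1)), c(125, 125, 125), "heatmap")
    v$brain_mask <- array(1, dim(v$data)); v$smoothed <- TRUE
    class(v) <- c("heatmap", class(v)); v
  }
  a <- mkhm(c(0.1, 0.2, 0.3, 0.4))
  expect_equal(correlate_heatmaps(a, a)$rho, 1.0)
  b <- mkhm(exp(-c(0.1, 0.2, 0.3, 0.4)))        # strictly decreasing map
  expect_equal(correlate_heatmaps(a, b)$rho, -1.0)
  # (1,2),(2,1),(3,3) -> rho = 0.5 by the hand-ranking oracle
  r <- correlate_heatmaps(mkhm(c(1, 2, 3)), mkhm(c(2, 1, 3)))
  expect_equal(r$rho, 0.5)
  expect_equal(r$n_voxels, 3L)
  # symmetric
  expect_equal(correlate_heatmaps(mkhm(c(1, 2, 3)), mkhm(c(2, 1, 3)))$rho,
               correlate_heatmaps(mkhm(c(2, 1, 3)), mkhm(c(1, 2, 3)))$rho)
  expect_error(correlate_heatmaps(a, mkhm(rep(0.5, 4))),
               class = "h3d_undefined_correlation")
})
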