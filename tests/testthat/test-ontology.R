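toy_ontology <- function() as_ontology(list(
  name = "brain", children = list(
    list(name = "forebrain", children = list(
      list(name = "cortex", labels = list(1L)),
      list(name = "striatum", labels = list(2L)))),
    list(name = "hindbrain", labels = list(3L)))))

grid_vols <- function(lab, st, vs = c(100, 100, 100)) {
  list(seg = volume(st, vs, "mask"), labels = volume(lab, vs, "label"))
}

test_that("ontology validation: duplicate labels, unlabelled leaves, labelled internals", {
  expect_error(as_ontology(list(name = "r", children = list(
    list(name = "a", labels = list(1L)), list(name = "b", labels = list(1L))))),
    class = "h3d_value_error")
  expect_error(as_ontology(list(name = "r", children = list(
    list(name = "a")))), class = "h3d_value_error")
  expect_error(as_ontology(list(name = "r", labels = list(9L), children = list(
    list(name = "a", labels = list(1L))))), class = "h3d_value_error")
  expect_setequal(ontology_labels(toy_ontology()), 1:3)
})

test_that("ontologies round-trip through JSON", {
  p <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(unclass(toy_ontology()), auto_unbox = TRUE), p)
  o2 <- read_ontology(p)
  expect_setequal(ontology_labels(o2), 1:3)
})

test_that("region_load computes percent occupancy with volumes in mm^3", {
  lab <- array(1L, c(10, 10, 10))
  st <- array(0, c(10, 10, 10)); st[1:50] <- 1
  gv <- grid_vols(lab, st)
  r <- region_load(gv$seg, gv$labels, 1L)
  expect_equal(r$load_pct, 5.0)
  expect_equal(r$region_volume_mm3, 1000 * 1e-3)
  # empty segmentation -> 0%; full -> 100%
  expect_equal(region_load(volume(array(0, c(10, 10, 10)), c(100, 100, 100), "mask"),
                           gv$labels, 1L)$load_pct, 0.0)
  expect_equal(region_load(volume(array(1, c(10, 10, 10)), c(100, 100, 100), "mask"),
                           gv$labels, 1L)$load_pct, 100.0)
  expect_error(region_load(gv$seg, gv$labels, 7L), class = "h3d_empty_roi")
})

test_that("invalid planes are excluded from regional quantification", {
  lab <- array(1L, c(4, 4, 3))
  st <- array(0, c(4, 4, 3)); st[, , 2] <- 1   # stain only on the bad plane
  seg <- volume(st, c(100, 100, 100), "mask",
                valid_planes = c(TRUE, FALSE, TRUE))
  r <- region_load(seg, volume(lab, c(100, 100, 100), "label"), 1L)
  expect_equal(r$load_pct, 0)
  expect_equal(r$n_roi_voxels, 32L)
})

test_that("internal-node loads are volume-weighted, never plain means of children", {
  # children volumes 1:3 with loads 40% and 0% -> parent load 10%
  lab <- array(0L, c(21, 1, 1)); st <- array(0, c(21, 1, 1))
  lab[1:5] <- 1L       # cortex: 5 voxels, 2 stained -> 40%
  lab[6:20] <- 2L      # striatum: 15 voxels, none stained -> 0%
  lab[21] <- 3L        # hindbrain present so the tree is fully populated
  st[1:2] <- 1
  gv <- grid_vols(lab, st)
  q <- ontology_quantify(gv$seg, gv$labels, toy_ontology())
  fb <- q[q$name == "forebrain", ]
  expect_equal(fb$load_pct, 10)   # (0.4 * 1 + 0 * 3) / 4 of the 20 voxels
  # equal-volume children with loads 10% and 20% -> parent 15%
  lab2 <- array(0L, c(20, 1, 1)); st2 <- array(0, c(20, 1, 1))
  lab2[1:10] <- 1L; lab2[11:20] <- 2L
  st2[1] <- 1; st2[11:12] <- 1
  q2 <- ontology_quantify(volume(st2, c(1, 1, 1) * 100, "mask"),
                          volume(lab2, c(1, 1, 1) * 100, "label"),
                          toy_ontology())
  expect_equal(q2$load_pct[q2$name == "forebrain"], 15)
})

test_that("conservation: parents are exact sums; root equals whole-brain load", {
  ph <- small_phantom()
  seg <- ph$markers$abeta$truth_mask
  q <- ontology_quantify(seg, ph$labels, ph$ontology)
  for (nm in c("telencephalon", "diencephalon", "brain")) {
    row <- q[q$name == nm, ]
    kids <- q[dirname(q$path) == row$path, ]
    if (nrow(kids)) {
      expect_identical(row$n_roi_voxels, sum(kids$n_roi_voxels))
      expect_identical(row$n_stained_voxels, sum(kids$n_stained_voxels))
    }
  }
  root <- q[q$depth == 0, ]
  wb <- region_load(seg, ph$labels, 1:6)
  expect_equal(root$load_pct, wb$load_pct, tolerance = 1e-12)
  expect_equal(root$region_volume_mm3, wb$region_volume_mm3)
})

test_that("quantification is invariant to rebalancing that preserves leaf partitioning", {
  ph <- small_phantom()
  seg <- ph$markers$abeta$truth_mask
  flat <- as_ontology(list(name = "brain", children = lapply(1:6, function(l)
    list(name = paste0("leaf", l), labels = list(l)))))
  q1 <- ontology_quantify(seg, ph$labels, ph$ontology)
  q2 <- ontology_quantify(seg, ph$labels, flat)
  expect_equal(q1$load_pct[q1$depth == 0], q2$load_pct[q2$depth == 0])
  expect_equal(sort(q1$n_stained_voxels[q1$is_leaf]),
               sort(q2$n_stained_voxels[q2$is_leaf]))
})

test_that("labels outside the ontology raise a coverage warning listing orphans", {
  lab <- array(c(1L, 2L, 3L, 9L), c(4, 1, 1))
  st <- array(0, c(4, 1, 1))
  gv <- grid_vols(lab, st)
  expect_warning(ontology_quantify(gv$seg, gv$labels, toy_ontology()),
                 regexp = "9")
})

test_that("absent leaves are reported with zero volume", {
  lab <- array(c(1L, 1L, 2L, 2L), c(4, 1, 1))   # no label 3 anywhere
  st <- array(c(1, 0, 0, 0), c(4, 1, 1))
  gv <- grid_vols(lab, st)
  q <- ontology_quantify(gv$seg, gv$labels, toy_ontology())
  hb <- q[q$name == "hindbrain", ]
  expect_equal(hb$n_roi_voxels, 0)
  expect_true(is.na(hb$load_pct))
})

test_that("self-parcellation returns the input labels and nearest-neighbour subsets", {
  ph <- small_phantom()
  bf <- apply_mask(ph$blockface, ph$tissue_mask)
  p <- parcellate(ph$mri, ph$labels, bf, ffd_grid = NULL, coarsen = 2L)
  agree <- mean(p$labels$data == ph$labels$data)
  expect_gte(agree, 0.97)
  expect_true(all(unique(as.integer(p$labels$data)) %in%
                    unique(as.integer(ph$labels$data))))
})

test_that("parcellation recovers labels through the known atlas warp (Dice >= 0.90)", {
  # mid-size phantom so that several regions exceed 1 mm^3
  ph <- make_phantom(phantom_spec(dims = c(96, 72, 40),
                                  voxel_size = c(25, 25, 125), seed = 0))
  bf <- apply_mask(ph$blockface, ph$tissue_mask)
  p <- parcellate(ph$atlas$intensity, ph$atlas$labels, bf,
                  ffd_grid = c(10, 10, 10), coarsen = 2L, max_iter = 40)
  vox_mm3 <- prod(ph$labels$voxel_size) * 1e-9
  checked <- 0L
  for (l in 1:6) {
    truth <- ph$labels$data == l
    if (sum(truth) * vox_mm3 < 1) next  # headline regions are >= 1 mm^3
    est <- p$labels$data == l
    dice <- 2 * sum(truth & est) / (sum(truth) + sum(est))
    expect_gte(dice, 0.90)
    checked <- checked + 1L
  }
  expect_gte(checked, 3L)
})

test_that("the shipped NeuroNames-style exemplar parses and covers the phantom labels", {
  p <- system.file("extdata", "ontology_neuronames_style.json", package = "histo3d")
  expect_true(file.exists(p))
  o <- read_ontology(p)
  labs <- ontology_labels(o)
  expect_true(all(1:6 %in% labs))           # the phantom's label values
  expect_gt(length(labs), 20)               # a fuller atlas is representable
})
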