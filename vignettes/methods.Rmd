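---
title: "3D whole-brain histopathology: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{3D whole-brain histopathology: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`histo3d` turns a shoebox of stained serial sections into quantitative 3D
maps of a histopathological marker.  This vignette explains the science the
package implements, the parameters that matter, and the design decisions
taken where a published protocol leaves details open.  Nothing here reports
an empirical result; the numbers the package produces come from its tests
and from `scripts/acceptance.R`.

## The measurement problem

Classical quantitative histopathology outlines a region of interest on a
handful of sections, measures the stained area fraction on each, and
extrapolates.  That protocol has two failure modes this package is built to
expose and avoid:

* **Sampling error.**  When a marker is distributed inhomogeneously along
  the rostro-caudal axis (a caudal hotspot, a gradient), a few equidistant
  sections can mis-estimate the regional load badly.  The
  `sampling_simulation()` machinery quantifies exactly this error, for any
  sampling period, against the all-sections reference.
* **Geometry loss.**  Mounted sections are individually rotated, sheared
  and translated.  Without a 3D reference there is no way to relate a
  section to an atlas or to in vivo imaging.  Block-face photographs, taken
  of the frozen block immediately before each section is cut, preserve the
  undeformed geometry and serve as the spatial reference for
  reconstruction.

## Data model

A `volume()` is a rank-3 voxel grid (rank-4 with a trailing RGB axis) with
physical voxel sizes in micrometres.  Axes are x = medio-lateral,
y = dorso-ventral, z = rostro-caudal; a coronal section is an x–y plane.
Indexing is 0-based with voxel centres at $(i + 0.5)\,d$ world micrometres:
an unambiguous convention that makes every resampling reproducible.

A `section_series()` records the sampling design: sections of thickness
$t$ µm with every $k$-th retained give reconstructed planes $t\,k$ µm
apart (the defaults, 25 µm and 1-in-5, give 125 µm).  Sections lost during
processing appear as gaps; `stack_sections()` zero-fills the missing planes
and flags them invalid, and every downstream quantification excludes
invalid planes rather than interpolating signal that was never observed.

## Reconstruction and registration

All transforms map *reference* world coordinates to *floating* world
coordinates (the pull-back convention): `resample(flo, t, grid)` fills each
target voxel `x` with `flo(t(x))`.  Estimation never needs transform
inversion, and label volumes are always pulled with nearest-neighbour
interpolation, which cannot invent labels.

**Section to block-face (2D affine).**  `register_section()` maximizes the
correlation coefficient by block matching on a three-level coarse-to-fine
pyramid.  Blocks with sufficient variance are matched exhaustively within a
search radius (with parabolic sub-pixel refinement); a trimmed
least-squares fit rejects mismatches.  Two design choices proved decisive
on low-texture sections and are worth recording:

* at the coarsest level only a translation is fitted (by robust median
  displacement) — the few coarse blocks cannot constrain an affine, and
  spatially structured mismatches otherwise leak into fake scale terms;
* the pyramid is initialized by principal-axes moments of the two tissue
  masks (Otsu threshold, centroid + second-moment orientation), which makes
  the rotation component observable before any block is matched.  The
  orientation term is disabled for nearly circular sections, where it is
  undefined.

Defaults: block size 21 px with 50% overlap, search radius 10 px at the
coarsest level halved per level, variance floor $(2\%$ of the intensity
range$)^2$, correspondences below correlation 0.3 discarded, 50% trimming.
All are exposed as arguments.

**Inter-volume (rigid, affine, elastic).**  The atlas chain estimates, on
intensity volumes, a rigid transform by mutual information (6 parameters,
derivative-free direction-set optimizer with centroid initialization), an
affine refinement by 3D block matching, and finally a free-form deformation:
displacements on a cubic B-spline control lattice (default
$10 \times 10 \times 10$, i.e. 3000 parameters) optimized by L-BFGS ascent
of the mutual information.  The MI gradient is computed by finite
differences with *local joint-histogram updates*: perturbing one control
point only moves samples inside its $4^3$-cell spline support, so a full
3000-parameter gradient costs a few histogram patches rather than 6000
metric evaluations.  MI uses 32 bins (64 for the generic
`mutual_information()`), natural base 2 (bits), background excluded by
masks.  Euler angles are intrinsic z–y–x in degrees, so printed transforms
are reproducible.

Transform estimation runs on volumes coarsened by an integer factor
(default 2) — standard practice, since the deformations being estimated are
smooth at the millimetre scale — while labels are always resampled at full
resolution.  Two further cross-modality safeguards in the atlas chain:
the atlas intensity volume is masked to its labelled support, so both
volumes present the same sharp brain/background edge (differing edge
profiles otherwise bias the block-matching scale estimate), and the affine
stage uses small blocks (default 5 voxels) because large blocks spanning
several anatomical boundaries weight those boundaries differently in the
two modalities and drag the fitted scale.

## Stain segmentation

The classifier is a supervised Bayes rule over per-pixel features
$(R, G, B, \ell)$ where $\ell$ is the local mean luminance over the
5-pixel in-plane cross (the centre pixel plus its 4-connected neighbours;
whether the centre is included is ambiguous in common descriptions of this
feature — we include it, switchable via `include_center`).  For each of
three classes — positively stained tissue, unstained tissue, background —
a multivariate Gaussian mixture is fitted by EM (k-means initialization
with a recorded seed, covariance ridge $10^{-3}$, per-iteration
log-likelihood asserted non-decreasing in the tests).  Three components per
class is the default; the phantom's classes are close to unimodal, but real
DAB staining benefits from multimodality (plaque core vs halo, background
glass vs embedding matrix, which are deliberately folded into one
background class).  Class priors default to labelled-pixel proportions.
Classification is per-section 2D (the features are in-plane), then stacked;
exact posterior ties break toward the earlier class in the declared order.

Evaluation uses precision $P = TP/(TP+FP)$, recall $R = TP/(TP+FN)$ and
$F_1 = 2PR/(P+R)$, each defined as 0 when its denominator is 0.

In the end-to-end pipeline, classification runs on the *reconstructed*
volume, whose pixels are colour mixtures produced by sub-pixel resampling.
The training set is therefore augmented with sub-pixel-shifted copies of
the annotation patches (shifts up to 0.35 px, labels unchanged), so the
fitted mixtures cover the blurred edge pixels the classifier will actually
see; without this, edge pixels of small stain objects systematically fall
to the unstained class and regional loads are biased low.  Block-face
planes with (almost) no tissue are stacked untouched — registering a
background-only section against a background-only photograph would fit a
transform to noise.

## Ontology-driven quantification

Marker *load* is the percentage of a region's volume occupied by segmented
staining.  `ontology_quantify()` counts stained and total voxels per leaf
region and rolls the *counts* up a NeuroNames-style hierarchy; an internal
node's load is recomputed from the summed counts (volume-weighted), never
averaged over children.  Conservation — parent counts exactly equal the sum
over children, root equals whole brain — is asserted in the tests.  Voxels
are assigned to regions by voxel-wise label identity; stain objects
straddling a boundary contribute to each side in proportion to their voxel
overlap.  Regions touching the volume boundary are quantified as-is.  A
~40-node exemplar hierarchy ships in
`inst/extdata/ontology_neuronames_style.json`.

## Heat maps and cross-marker correlation

`occupancy_heatmap()` aggregates the binary high-resolution segmentation
into low-resolution voxels (default 125 µm isotropic) holding the staining
occupation ratio.  Aggregation is exact integer bookkeeping: the numerator
and denominator counts are kept, so the pre-smoothing identity
$\sum \text{value} \times \text{covered} = \text{stained voxel count}$
holds to machine precision.  Boundary voxels use the covered-voxel
denominator (not the full tile), avoiding rim underestimation; the heat-map
brain mask flags voxels with at least half their support in tissue.  In z,
the reconstructed spacing usually already equals the target; otherwise
whole planes are averaged into slabs with plane-validity weights.

Gaussian smoothing uses a kernel matched to the heat-map voxel: "kernel
size equal to the voxel size" is ambiguous between σ and FWHM, so σ = 1
voxel is the default with `kernel = "fwhm"` as the alternative.  Smoothing
is mask-normalized (filtered numerator over filtered mask), so constant
maps are fixed points and no mass bleeds outside the brain.

Markers are compared voxel-wise by Spearman's rank correlation (average
ranks for ties, two-sided p) over the masked heat maps, which all live on
the block-face grid — no per-marker resampling.

## Section-sampling simulation

For each sampling period $k$, every phase offset $o \in \{0..k-1\}$ yields
one subset of the valid sections; subsets are disjoint and exhaustive.
A subset's load pools counts over its sections (as 2D protocols pool
outlined areas — whether historical protocols pooled or averaged is rarely
stated; pooling is our declared convention), and its relative error is
$RE = 100\,|L_{subset} - L_{full}|\,/\,L_{full}$.  Rostro-caudal dispersion
is summarized by the coefficient of variation of per-section loads, with
the sample (n−1) standard deviation.  Sections where the ROI is absent are
excluded, not counted as zero.

## The phantom: what it emulates, what it does not

`make_phantom()` builds a complete synthetic study, deterministic given its
seed: an ellipsoidal brain (128 × 96 × 60 voxels at 25 × 25 × 125 µm,
mirroring the 25 µm / every-5th design) with six labelled regions under a
three-level ontology; a block-face volume (tissue darker than the bright
embedding, with regional and smooth textural contrast); an MRI-like atlas
in a space related to the block-face space by a known affine plus smooth
elastic warp; amyloid-plaque-like stain blobs with lognormal radii around
45 µm, per-region densities of 0.5–5% and per-region rostro-caudal
profiles (uniform cortex/striatum, hippocampal gradient, caudal thalamic
hotspot — the qualitative pattern that makes sparse sampling fail where it
should); a second marker colocalized with the first (80% of its blobs
seeded at partner blobs) for the cross-marker correlation analysis; and
per-section affine distortions (±4°, ±3% shear, ±10 px) with the true
transforms retained, so registration accuracy is measurable exactly.
Rendered sections show anatomy through counterstain-like regional shading,
as real sections do.

The phantom does **not** emulate: vascular or cellular texture, staining
artefacts (folds, tears, bubbles), illumination fields, chromatic noise
correlations, or partial-volume stain intensity.  Tests passing on the
phantom therefore demonstrate the correctness of the pipeline's geometry,
statistics and bookkeeping — not segmentation robustness on real slides,
which must be re-validated per marker with real annotated patches.

## Problem sizes and numerical choices

The unit-test phantom is 64 × 48 × 20 voxels; the full study (acceptance
script and end-to-end determinism test) uses the 128 × 96 × 60 default.
Atlas registration estimates transforms at coarsening factor 2 with 30
L-BFGS iterations for the elastic stage.  These sizes were chosen so the
whole suite exercises every stage at realistic anisotropy while remaining
routine desk-scale computation.

Degenerate inputs are errors, not silent results: constant volumes cannot
be thresholded or correlated, empty ROIs have no load, a zero mean load has
no CV, and a zero reference load has no relative error.  All errors carry
typed condition classes (`h3d_*`) so callers can handle them precisely.

## Known limitations

* The 2D registration model is affine; strong local section distortion
  (tears, folds) is out of scope, though the per-section elastic hook in
  the phantom allows studying its effect.
* FFD inversion is not provided; all pipeline paths are arranged to need
  only pull-backs.
* Mutual information uses dense histograms; very small overlaps (< a few
  hundred voxels) make it unreliable, and the estimators flag
  non-convergence rather than guessing.
* Group comparison is a single Mann–Whitney test per call; multiple-testing
  control across many regions is deliberately the caller's concern.
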