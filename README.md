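# histo3d

3D whole-brain quantitative histopathology in R: reconstruct serial
stained sections into block-face-referenced 3D volumes, segment
immunohistochemical stainings with a supervised Gaussian-mixture pixel
classifier, parcellate the brain with an atlas and a hierarchical
anatomical ontology, quantify marker load per region, build low-resolution
occupancy heat maps for voxel-wise cross-marker correlation, and measure
how badly sparse 2D section sampling estimates 3D regional loads.

## Who this is for

Labs quantifying a histological marker (amyloid-β plaques, microglia,
phagocytic cells, Nissl bodies, ...) across whole rodent brains from serial
coronal sections, and anyone who needs ground-truthed synthetic data to
validate such a pipeline: a built-in phantom generator produces a complete
fake study — block-face volume, distorted stained sections, stain masks,
true transforms, toy atlas and ontology — so every stage is testable
against known truth.

## The method

1. **Reconstruction.** Block-face photographs, taken of the frozen block
   before each section is cut, preserve the undeformed brain geometry.
   Each stained section is registered to its block-face plane by 2D affine
   block matching (correlation coefficient, three resolution levels),
   undoing the rotations, shears and translations introduced by
   sectioning and mounting.
2. **Segmentation.** Per pixel, the features (R, G, B, local mean
   luminance over the 4-connected cross) feed a Bayes classifier with one
   Gaussian mixture per class — stained tissue, unstained tissue,
   background — fitted by EM on expert-labelled patches. Quality is
   scored by F1 = 2PR/(P+R) against held-out annotations.
3. **Parcellation.** An atlas (intensity + label volumes) is registered to
   the block-face volume by a rigid (mutual information, direction-set
   optimizer), affine (3D block matching) and free-form-deformation stage
   (cubic B-spline lattice, default 10×10×10 control points, MI maximized
   by L-BFGS); labels are pulled onto the block-face grid with
   nearest-neighbour interpolation.
4. **Quantification.** Marker *load* = percentage of a region's volume
   occupied by staining; loads roll up a NeuroNames-style ontology by
   exact voxel-count sums (volume-weighted, conservative).
5. **Heat maps and correlation.** Binary segmentations aggregate into
   125 µm isotropic occupancy-fraction voxels, Gaussian-smoothed with a
   kernel matched to the voxel size; markers are compared voxel-wise by
   Spearman's ρ.
6. **Sampling simulation.** For every sampling period k, all k
   phase-offset subsets of sections are quantified and compared with the
   all-sections reference through RE = 100·|L_subset − L_full|/L_full,
   the error a sparse 2D protocol would have made.

The methods vignette (`vignettes/methods.Rmd`) details every model,
parameter and design decision.

## Worked example

Quantify a synthetic study's ground-truth masks through the ontology, and
see why sparse sampling fails on an inhomogeneous region:

```r
library(histo3d)
ph <- make_phantom(phantom_spec(dims = c(64, 48, 20),
                                voxel_size = c(25, 25, 125), seed = 1))
q <- ontology_quantify(ph$markers$abeta$truth_mask, ph$labels, ph$ontology)
q[q$depth <= 1, c("path", "region_volume_mm3", "stained_volume_mm3", "load_pct")]
#>                 path region_volume_mm3 stained_volume_mm3 load_pct
#>                brain            1.7431            0.09172     5.26
#>   brain/diencephalon            0.0408            0.00234     5.75
#>    brain/other_brain            0.2487            0.00836     3.36
#>  brain/telencephalon            1.4536            0.08102     5.57
```

The whole-brain amyloid-like load is 5.26% of tissue volume, and the
internal-node loads are the volume-weighted roll-ups of their leaves.
Now simulate discarding sections, for a rostro-caudally uniform ROI
(cortex) and for one whose marker concentrates in a caudal hotspot
(thalamus):

```r
for (l in c(cortex = 1L, thalamus = 5L)) {
  sim <- sampling_simulation(ph$markers$abeta$truth_mask, ph$labels, l,
                             steps = c(1, 3, 6))
  print(attr(sim, "summary"))
}
#>  k spacing_mm n_subsets median_re q1_re q3_re     (cortex)
#>  1      0.125         1      0.00  0.00  0.00
#>  3      0.375         3      2.53  2.32  3.69
#>  6      0.750         6      6.39  4.71  8.71
#>  k spacing_mm n_subsets median_re q1_re q3_re     (thalamus)
#>  1      0.125         1         0   0.0     0
#>  3      0.375         3       100  50.8   105
#>  6      0.750         5       100 100.0   100
```

With every section (k = 1) the error is zero by construction. In the
uniform cortex, 1-in-6 sampling mis-estimates the load by a median 6%; in
the hotspot-bearing thalamus, subsets that miss the hotspot report almost
no staining — a median relative error of 100%. Finally, two markers whose
blobs were generated colocalized correlate voxel-wise in their heat maps:

```r
hm_a <- occupancy_heatmap(ph$markers$abeta$truth_mask, 125,
                          tissue_mask = ph$tissue_mask)
hm_p <- occupancy_heatmap(ph$markers$phago$truth_mask, 125,
                          tissue_mask = ph$tissue_mask)
correlate_heatmaps(smooth_heatmap(hm_a), smooth_heatmap(hm_p))
#> Spearman rho = 0.37 (p = 1.2e-30, n = 902 heat-map voxels)
```

The full pipeline — reconstruction, training, segmentation, atlas
registration, quantification, heat maps, correlations, sampling — runs in
one call:

```r
run_pipeline(pipeline_config(out_dir = "study_out", seed = 1))
```

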