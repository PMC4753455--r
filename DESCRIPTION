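Package: histo3d
Title: Three-Dimensional Reconstruction and Quantitative Analysis of
    Serial-Section Brain Histology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Reconstructs stacks of stained serial histological sections
    into coherent 3D volumes using block-face photographs as an undeformed
    spatial reference, segments immunohistochemical stainings with a
    supervised Gaussian-mixture pixel classifier, parcellates the
    reconstructed brain by registering an atlas (rigid, affine and
    free-form-deformation stages), quantifies marker load in a
    hierarchical anatomical ontology, converts segmentations into
    low-resolution occupancy heat maps for voxel-wise cross-marker
    correlation, and simulates the quantification error incurred by
    sparse 2D section sampling.  A synthetic phantom-brain generator
    provides a complete fake study with ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
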