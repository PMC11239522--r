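Package: cellmapr
Title: Whole-Brain Cell Mapping for Cleared-Tissue Light-Sheet Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, desk-scale pipeline for detecting immunolabeled
    cells (for example c-Fos+ nuclei) in three-dimensional light-sheet image
    stacks of cleared mouse brains and mapping them to a hierarchical brain
    atlas. Provides ventricle masking with a random-forest voxel classifier,
    a 3D encoder-decoder convolutional network with sliding-window inference
    for cell segmentation, connected-component instance extraction with size
    filtering, affine registration and atlas region assignment, level-aware
    group statistics with Benjamini-Hochberg correction, instance-level
    segmentation metrics, visualization in image and atlas space, and a
    synthetic cleared-brain generator with known ground truth so the whole
    pipeline is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    tiff,
    ranger,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
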