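Package: slakit
Title: Quantitative Analysis of Bacterial S-Layer Self-Assembly Imaging and Tracking Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying surface-layer (S-layer) protein self-assembly
    on bacterial cells from super-resolution microscopy and single-molecule
    tracking experiments. Implements axial binary cell-profile analysis of
    two-color STED-like images with Wilson score confidence bands, detection and
    photon-based molecule counting of crystal puncta, sliding-window RMSD
    classification of single-molecule tracks into bound and unbound states with
    distance-to-seed co-occupancy summaries, pooled 3D mean-squared-displacement
    diffusion estimation corrected for camera exposure blur and localization
    error, and discrete Gaussian curvature of cell-surface triangle meshes.
    Includes synthetic-data generators (Brownian trajectories with binding and
    motion blur, two-color cell images with known label patterns, spherocylinder
    meshes) so that every stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
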