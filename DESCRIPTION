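Package: vesselmesh
Title: Scale-Adaptive Surface Reconstruction of Segmented Vascular Structures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Model-free surface reconstruction for binary vessel
    segmentations. Extracts an oriented boundary point cloud from a 3D
    occupancy volume (with subvoxel refinement near thin branches detected by
    a morphological top-hat transform), computes a Poisson indicator function
    on a regular B-spline basis, and polygonizes its level set with a
    curvature-adaptive mesh-expanding algorithm followed by minimum-weight
    dynamic-programming gap stitching. Includes analytic phantoms (sphere,
    tube, torus, Y-bifurcation, dumbbell) with exact signed distances, mesh
    and volume I/O (NIfTI, MetaImage, raw; PLY, OBJ, STL), and mesh quality
    metrics (edge-ratio histograms, RMS principal curvature, sampled
    Hausdorff-style distances, topology reports).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
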