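Package: planepose
Title: Plane Pose Regression in 3D Ultrasound Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the six-dimensional pose (3D translation and
    3D rotation) of a 2D ultrasound imaging plane relative to the centre of a
    3D volume, using a regression convolutional neural network with a
    continuous 6D rotation representation recovered by Gram-Schmidt
    orthonormalization. Includes SO(3) geometry utilities (6D representation,
    Euler conversions, geodesic distance), an oblique-plane slicer with
    trilinear interpolation, a procedural fetal-brain-like speckle phantom
    generator, dataset construction with random and near-standard-plane pose
    sampling, CNN training with a weighted rotation/translation loss, and
    evaluation with per-subset median/min/max error reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
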