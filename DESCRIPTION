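Package: rtcbct
Title: Real-Time Dynamic Cone-Beam CT Reconstruction and Single-Projection
    Motion Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs a dynamic (time-resolved) cone-beam CT sequence from a
    single pre-treatment cone-beam scan by jointly estimating a static reference
    anatomy, represented by a hash-encoded implicit neural representation, and a
    data-driven low-rank respiratory motion model built from multi-level B-spline
    motion basis components. A lightweight convolutional motion encoder is trained
    alongside the reconstruction so that, at treatment time, the three-dimensional
    motion state and a volumetric image can be estimated in real time from one
    x-ray projection acquired at an arbitrary gantry angle. Includes a
    differentiable cone-beam projector with Feldkamp-Davis-Kress warm start, an
    analytic dynamic thorax phantom for simulation studies with ground-truth
    deformation fields, markerless tumor tracking by contour propagation, and
    image-quality and tracking metrics (relative error, SSIM, center-of-mass
    error, Dice, Amsterdam-Shroud respiratory traces).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
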