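Package: tomoPLS
Title: Discrete Tomography Reconstruction with Parametric Level Sets and
    Compressed Sensing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstruction of piecewise-constant images with a small set of
    known gray levels from sparse-view and limited-angle parallel-beam
    tomographic projections. The object boundary is represented by a
    parametric level set expanded in a dictionary of Gaussian radial basis
    functions (single-scale or multiscale), and the basis coefficients are
    estimated by l1-regularized least squares solved with an orthant-wise
    limited-memory quasi-Newton (OWL-QN) algorithm. Includes an exact
    ray-driven system-matrix builder, synthetic phantom and noise
    simulation, filtered backprojection and total-variation
    (Chambolle-Pock) baselines, and PSNR/SSIM/Dice quality metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    stats,
    utils,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
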