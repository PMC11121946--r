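Package: cryocn
Title: Unsupervised Missing-Wedge Tomogram Reconstruction with Coordinate
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulation, reconstruction and evaluation tools for the
    missing-wedge problem in cryo-electron tomography. Provides binary
    phantom generators and a differentiable parallel-beam projector for
    tilt-series simulation; an unsupervised reconstruction method that
    fits sinusoidal-activation coordinate networks directly to the
    projections, one network per y-axis subvolume with learned
    initializations; a minimal weighted-back-projection baseline; and a
    reference-based evaluation suite (PSNR, SSIM, VIF, Fourier shell
    correlation) including a directional FSC restricted to the present or
    missing regions of Fourier space. Volumes and tilt series are read
    and written as MRC2014, tilt angles as plain-text angle files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Matrix,
    methods,
    Rcpp,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
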