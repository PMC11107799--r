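Package: useweb
Title: Wideband Shear-Wave Phase-Velocity Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Two-dimensional shear-wave phase-velocity imaging of soft
    tissues over an expanded frequency bandwidth. Implements the USEWEB
    reconstruction (generalized Stockwell transform combined with
    short-space slant wavenumber-frequency analysis), the local phase
    velocity imaging (LPVI) baseline with an optional Butterworth
    wavenumber filter, one-dimensional dispersion estimation (2D Fourier
    and slant-stack variants), viscoelastic material models (Kelvin-Voigt
    and standard linear solid) with nonlinear least-squares
    identification, a dispersive shear wavefield simulator with known
    ground truth, and image-quality metrics (coefficient of variation,
    contrast-to-noise ratio, cross-section profiles).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    Rcpp,
    minpack.lm,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
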