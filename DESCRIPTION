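Package: dwiharm
Title: Cross-Scanner Harmonisation of Diffusion MRI with Spherical
    Harmonics, Sparse Dictionaries and Voxel-Wise Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping diffusion-weighted MRI between scanners and
    acquisition protocols. Implements a real even-order spherical-harmonic
    (SH) representation with Laplace-Beltrami regularisation, weighted
    linear least-squares diffusion tensor estimation with FA/MD maps,
    rotationally invariant SH (RISH) energy features R0/R2, a reference
    predictor based on trilinear and SH interpolation, a sparse
    dictionary-learning harmoniser with non-negative coding and AIC-driven
    sparsity selection, a voxel-wise multilayer-perceptron harmoniser on
    order-4 SH coefficients, a three-scale (global/regional/local)
    ME/MNE/MSE evaluation protocol with poor-region flagging, and a
    synthetic travelling-subject phantom generator so the full pipeline is
    testable without access to restricted human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    Rcpp,
    pracma,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
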