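Package: pulmem
Title: Inverse Finite Element Analysis of Lung Surface Membrane Mechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reduced-order membrane model of the lung surface with an inverse
    finite element analysis (IFEA) engine for calibrating constitutive
    parameters against full-field surface displacement measurements such as
    those produced by digital image correlation (DIC). Provides a nonlinear
    quasi-static membrane solver with follower pressure loading, three
    constitutive laws (compressible Mooney-Rivlin, Holzapfel-Gasser-Ogden
    with fiber dispersion, and heterogeneous isotropic linear elasticity),
    k-nearest-neighbor displacement-field interpolation with cross-validated
    accuracy reporting, adjoint-method and finite-difference objective
    gradients, multi-start bounded least-squares calibration, a particle
    swarm optimizer with bound clamping, and a synthetic-scenario generator
    for parameter-recovery verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    methods,
    parallel,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
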