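Package: cardiogrow
Title: Inverse Characterization of Left-Ventricular Myocardial Growth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward finite-element modeling of kinematic myocardial growth
    (transverse and longitudinal cardiomyocyte hypertrophy) on idealized
    left-ventricular geometries, and inverse estimation of the two growth
    coefficients from a target post-growth geometry.  Includes a truncated
    prolate-spheroid hexahedral mesh generator with a butterfly apex,
    Laplace-Dirichlet rule-based fiber assignment, a Holzapfel-Ogden
    anisotropic hyperelastic material with a multiplicative growth
    decomposition, a quasi-static explicit (dynamic relaxation) solver with
    endocardial pressure loading and pericardial penalty contact, B-spline
    kernel voxelization with DICE scoring and rigid (ICP) registration, and
    a Gaussian-process Bayesian optimization loop with an upper confidence
    bound acquisition.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    splines,
    xml2,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
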