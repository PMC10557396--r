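Package: cranioface
Title: Craniofacial Soft-Tissue Modelling and Computerized Facial Approximation
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying craniofacial hard/soft-tissue relationships
    and generating approximated faces from dry-skull surface meshes. Implements
    dense facial soft-tissue depth (FSTD) fields measured along fixed
    directions, generalized Procrustes analysis, shape PCA, two-block partial
    least squares with RV coefficients and permutation tests, ridge regression
    from hard- to soft-tissue shape scores, thin-plate-spline and non-rigid
    ICP template registration, statistical-shape-model fitting, and Laplacian
    mesh refinement, together with a synthetic paired skull/face cohort
    generator for end-to-end validation without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
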