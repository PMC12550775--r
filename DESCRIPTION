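Package: stemfea
Title: Patient-Specific Finite-Element Evaluation of Tibial Extension Stems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale finite-element pipeline for comparing tibial
    extension stem configurations in total knee arthroplasty. Generates a
    synthetic CT phantom of a proximal tibia with known ground-truth density,
    performs virtual surgery (oblique resection, parametric implant, cavity
    carving), builds conformal quadratic tetrahedral (TET10) meshes on a
    structured background grid, maps Hounsfield units to heterogeneous
    elastic moduli via Gaussian quadrature and density-modulus power laws,
    solves the linear-elastic problem under physiological compressive load
    cases, and post-processes von Mises stress, equivalent elastic strain,
    principal strains, and a strain-based periprosthetic fracture-risk
    statistic, including region-of-interest micro-strain percentiles.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Matrix,
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    mgcv,
    igraph,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
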