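Package: sonoplan
Title: Treatment Planning and Setup Optimization for Ultrasound-Guided
    Robotic Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study robotic ultrasound guidance in robotic
    stereotactic radiotherapy of the prostate. Generates synthetic pelvic
    CT phantoms with target and organ-at-risk structures, samples
    candidate treatment beams and computes water-equivalent (radiological)
    path lengths, solves the two-stage linear-programming inverse planning
    problem (coverage maximization by underdose minimization under hard
    maximum-dose constraints, followed by monitor-unit minimization at
    fixed per-voxel dose lower bounds), enumerates acoustically feasible
    ultrasound viewports by ray tracing CT gray values, models the
    transducer-carrying robot arm as a capsule chain with an elbow
    redundancy (LIFT) circle and decides beam blocking by clearance
    geometry, trains a small convolutional network with a
    coverage-weighted loss to score candidate beams and samples beams by
    predicted weight, and optimizes the robot base position, viewport and
    LIFT angle by simulated annealing under blocked-beam objectives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    RNifti
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
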