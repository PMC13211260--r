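Package: cowflow
Title: Multiscale 0D-1D Hemodynamics of the Circle of Willis with
    Cerebral Autoregulation and Path-Flow Decomposition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coupled 0D-1D simulation of the cardio-cerebrovascular
    circulation: a lumped time-varying-elastance heart drives a Poiseuille
    resistance network over a Circle-of-Willis arterial graph whose outlets
    are regulated by an iterative cerebral-autoregulation boundary model;
    one-dimensional compliant-tube flow in every segment feeds effective
    resistances back into the network until cycle-to-cycle convergence.
    Localized stenoses enter through the Young-Tsai flow-dependent pressure
    drop.  A post-processing module decomposes the converged segment flows
    into nonnegative source-to-sink path flows by depth-first-search path
    enumeration and an L1- plus pumping-cost-regularized convex inversion,
    yielding source-to-territory attribution matrices and a multiplicative
    noise robustness study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Matrix,
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
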