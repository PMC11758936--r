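Package: msconnectome
Title: Structural Disconnection and Morphometric Similarity Networks from
    Conventional MRI in Multiple Sclerosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Atlas-based structural disconnectomes from binary lesion masks,
    cortical morphometric similarity networks from vertex-level features via
    symmetrized Kullback-Leibler divergence (the MIND approach), network-based
    statistics with permutation family-wise error control (cross-sectional
    general linear models and longitudinal linear mixed models),
    connectome-based prediction of confirmed disability progression with
    nested cross-validation and cross-validated deconfounding, and multi-scale
    coupling between the two network domains.  A synthetic cohort generator
    with plantable subnetwork effects makes the full pipeline testable
    without any real MRI data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    igraph,
    MASS,
    e1071,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), lme4
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
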