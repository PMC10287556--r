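Package: stabcca
Title: Stability-Selected Sparse Canonical Correlation Pipelines for
    Multi-View Exposome, Brain and Genetic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements a multi-stage inference pipeline linking
    high-dimensional environmental exposure profiles to psychiatric
    symptom groups: latent-category construction by cross-validated
    one-factor confirmatory factor analysis, stability-selected sparse
    canonical correlation analysis (penalized matrix decomposition) with
    projection deflation and permutation inference, three-block sparse
    CCA with regional brain volumes, additive-dosage association scans
    with greedy LD clumping and weighted gene scores, and
    genotype-moderated brain-mediated pathway (moderated mediation)
    analysis with bias-corrected bootstrap intervals.  A synthetic
    multi-view data generator with known planted structure makes every
    stage testable without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    caret,
    vcfR,
    withr
Config/testthat/edition: 3
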