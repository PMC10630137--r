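Package: perturbOT
Title: Single-Cell Perturbation Response Prediction via Neural Optimal Transport
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Learns per-perturbation optimal transport maps between unpaired
    control and perturbed single-cell populations by optimizing a pair of
    input-convex neural potentials in the Kantorovich dual, and predicts
    per-cell responses as the gradient of the learned convex potential.
    Ships the surrounding pipeline: reading and writing annotated
    cells-by-features matrices (delimited text and H5AD), library-size and
    percentile normalization, highly-variable-gene selection, train/test
    splits including out-of-sample and out-of-distribution protocols, an
    autoencoder latent space for high-dimensional transcriptomes,
    distribution-level evaluation (multi-bandwidth unbiased maximum mean
    discrepancy, feature-mean distances, marker-gene restriction), and
    synthetic generators with closed-form Gaussian and exact discrete
    optimal-transport oracles for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    stats,
    utils,
    generics,
    ggplot2,
    readr,
    yaml,
    jsonlite,
    clue,
    rhdf5
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
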