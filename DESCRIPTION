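Package: cnelink
Title: Linking Substitution Rate Shifts in Conserved Elements to Rates of
    Continuous Trait Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Bayesian phylogenetic model that assigns latent conservation
    states (background, conserved, accelerated) to the branches of a rooted
    tree and couples per-state nucleotide substitution rate multipliers to
    per-state variance multipliers of a Brownian-motion continuous trait.
    Inference is by collapsed Gibbs sampling with Metropolis-within-Gibbs
    steps over ancestral nucleotides, ancestral trait values, conservation
    states and model parameters. Elements are ranked by a Savage-Dickey
    density-ratio Bayes factor contrasting the full model against a null in
    which trait variance is decoupled from the substitution process. A
    generative simulator for alignments, traits and conservation states
    supports calibration and false-positive-rate studies.
License: GPL (>= 3)
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    optparse
Config/testthat/edition: 3
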