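Package: gpsmeval
Title: Evaluating Generative Protein Sequence Models with Higher-Order
    Marginal Statistics and Phylogenetic Corrections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for benchmarking generative protein sequence models
    (GPSMs) on multiple sequence alignments. Implements pairwise identity
    filtering and phylogeny-aware training/reference splits, Potts
    (pairwise coupling) and site-independent models with marginal-matching
    inference and Metropolis MCMC sequence generation, the r20 and
    connected-correlation r20 statistics over higher-order marginals, a
    finite-sampling null model, and synthetic-data generators producing
    i.i.d. and phylogenetically clustered alignments from known coupling
    landscapes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
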