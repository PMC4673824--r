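Package: hgtsweep
Title: Eco-Evolutionary Models of Horizontal Gene Sweeps Under Migration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates the spread of a horizontally transferable beneficial
    allele through a microbial community under selection, gene transfer and
    immigration. Provides a deterministic two-compartment (carrier versus
    non-carrier) model with an extended two-patch variant, a backward-in-time
    six-state pair-coalescence calculator of focal-locus and
    background-genome diversity, a stochastic niche-structured Wright-Fisher
    individual-based model with horizontal transfer and migration, order-2
    Hill-number diversity metrics, and drivers that regenerate the
    quantitative experiments (cumulative gene flux, carrier fraction and
    diversity-ratio scans) from parameter configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
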