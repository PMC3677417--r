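Package: mtkinetics
Title: Kinetic Models of Microtubule Dynamic Instability and Multistep Catastrophe
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic and analytic kinetic models of microtubule plus-end
    dynamics. Provides exact event-driven (Gillespie) simulators of single
    protofilaments under coupled, vectorial, random and coupled-random
    GTP-hydrolysis mechanisms with pluggable catastrophe rules; an analytically
    solvable multi-protofilament coupled-random model in which catastrophe is
    the n-th of N protofilament destabilization events (order statistics of
    exponential step times); predictions for tubulin-dilution experiments;
    maximum-likelihood fitting of single-microtubule lifetime data with model
    selection over the number of destabilizing steps; and a synthetic-data
    generator with the model's exact statistical structure. A command-line
    interface exposes the main computations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
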