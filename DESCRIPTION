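Package: grnsim
Title: Stochastic Simulation of Gene Expression from Regulatory Networks
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Compiles directed, signed gene regulatory networks into delayed
    chemical-reaction systems (promoters, RNAs, proteins) and simulates them
    with a time-delayed stochastic simulation algorithm (Gillespie direct
    method with a time-ordered wait list). Produces time-series and
    steady-state-ensemble expression matrices of molecule counts suitable for
    benchmarking network-inference methods, parses and emits a plain-text
    mass-action reaction grammar with per-product delay annotations, and
    includes mutual-information based diagnostics that check whether simulated
    expression encodes the generating topology.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
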