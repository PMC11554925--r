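Package: dcfba
Title: Dynamic-Control Flux Balance Analysis for Two-Stage Butanediol Bioprocess Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Constraint-based design of two-stage 2,3-butanediol fermentation
    processes. Builds a small stoichiometric model of an engineered
    Escherichia coli production strain, fits an affine production envelope
    (glucose uptake, diol secretion and minimal acetoin exchange as functions
    of growth rate) from two-stage fed-batch time series, and optimizes
    fed-batch processes by direct optimal control (orthogonal collocation on
    moving finite elements) with an independent two-stage switch-time oracle.
    Maps the titer-productivity design space into proportionality and
    trade-off regions, extracts and fits the Pareto front, and optimizes a
    continuous two-reactor (aerobic/microaerobic) chemostat cascade at steady
    state. Includes a synthetic fed-batch data generator with pulsed feeding,
    lag phase and multiplicative measurement noise so that the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    deSolve,
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
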