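Package: endosim
Title: Population-Based Stochastic Modelling of hESC Endoderm Induction
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Agent-based stochastic simulation of human embryonic stem cell
    (hESC) differentiation during endoderm induction, with tools for mechanism
    selection. Cells carry a signalling-regime affinity, lifespan, cell-cycle
    clock and per-lineage commitment propensities, and evolve under
    proliferation, death and differentiation rules. The package enumerates
    twelve candidate differentiation mechanisms (mesendoderm intermediate,
    CXCR4 expression in mesoderm, phenotype-restricted proliferation),
    performs histogram-distance parameter sensitivity analysis with
    Freedman-Diaconis binning, fits each mechanism to daily Sox17/CXCR4
    marker dynamics by random-sampling ensemble least squares, runs
    two-dimensional convergence studies over initial population size and
    replicate count, and generates synthetic calibration data emulating the
    experimental time courses for two induction conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
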