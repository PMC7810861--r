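Package: grnconv
Title: Quantitative Modelling of the Gene Regulatory Network Driving
    Direct Fibroblast-to-Neuron Reprogramming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds thermodynamic (Shea-Ackers) ordinary differential
    equation models of the small gene regulatory network that controls
    direct conversion of human fibroblasts to induced neurons (PTB, nPTB,
    miR-124/miR-9, the REST complex and Ascl1), simulates the three-stage
    conversion protocol (fibroblast, REST knockdown, viral conversion)
    deterministically (fixed-step RK4) and stochastically (Gillespie with
    tunable noise granularity), fits parameters to replicated qPCR-style
    time series with a real-valued genetic algorithm, enumerates and
    compares alternative network topologies, runs in-silico
    overexpression/knockdown scenario grids with a conversion classifier,
    and dissects instantaneous transcription rates into per-regulator
    "arrow" contributions.  A synthetic-data generator emulates the
    structure of the experimental time series so the whole pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    xml2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite
Config/testthat/edition: 3
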