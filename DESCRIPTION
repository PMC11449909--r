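Package: ornpulse
Title: Duration Encoding in Pheromone-Sensitive Olfactory Receptor Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models and analysis tools for pheromone-evoked responses of
    moth olfactory receptor neurons (ORNs): receptor binding/activation
    kinetics that generate the local field potential (LFP), a
    linear-nonlinear model predicting firing rate from the LFP with
    exponential adaptation kernels, a single-glomerulus antennal-lobe
    spiking network with SK-conductance adaptation, a passive
    multicompartmental sensillum model with inverse current estimation,
    spike-train statistics (adaptive-bandwidth kernel rate estimation,
    response-end detection, inhibitory and rebound phase comparisons), and
    a synthetic-cohort generator emulating single-sensillum recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    signal,
    deSolve,
    glmnet,
    Matrix,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
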