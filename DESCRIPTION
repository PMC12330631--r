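Package: photocircuit
Title: Prefrontal Microcircuit Simulation and Spectral Fiber-Photometry Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying disinhibitory VIP-SST-PV microcircuit dynamics in
    medial prefrontal cortex and their readout by spectrometer-based fiber
    photometry. Provides a 36-neuron leaky integrate-and-fire network model
    driven by stochastic ventral-hippocampal input, with a synaptic weight-sweep
    experiment; a spectral photometry processing chain (band summation, linear
    unmixing, detrending, delta-F-over-F, ratiometric per-trial z-scoring,
    MAD-thresholded calcium-transient detection, peri-event alignment,
    distal-delay scoring, and lagged cross-correlation); pointwise functional
    regression of trial-level calcium signals with mouse-clustered bootstrap
    pointwise and joint confidence bands; scoring of delayed non-match-to-sample
    spatial working-memory training; and a synthetic-data generator that
    produces all inputs with ground truth attached.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml,
    rlang,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
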