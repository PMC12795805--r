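Package: eislope
Title: Spectral Slope of Simulated Population Activity and Excitation-Inhibition Balance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based leaky integrate-and-fire network simulations of
    two recurrent motifs (the subthalamic nucleus - globus pallidus externa loop
    and a neocortical excitatory-inhibitory network), an LFP proxy built from
    summed synaptic currents, Welch power spectra, an entropy-based oscillation
    index, and aperiodic (1/f) exponent estimation by spectral parameterization.
    Provides parameter-sweep orchestration, perturbation experiments with
    transition-angle statistics, EI-conductance-ratio analysis, and a surrogate
    signal generator with known aperiodic exponent for validating the spectral
    pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
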