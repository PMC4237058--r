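Package: rainstp
Title: Short-Term Plasticity Characterization and Self-Sustaining Spiking
    Network Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analyzing Tsodyks-Markram short-term synaptic
    plasticity (STP). Provides the closed-form critical presynaptic firing
    rate separating facilitating from depressing regimes, steady-state and
    event-driven synapse dynamics with fixed-point calibration of the
    synaptic scale constant, partitioning of the (U, tau_D, tau_F) parameter
    space into brain-rhythm classes, a conductance-based leaky
    integrate-and-fire network simulator with optional STP-modulated
    synapses, the jump-start protocol for self-sustained random asynchronous
    irregular network (RAIN) activity, and a characterization-guided search
    for STP parameters that sustain such activity.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
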