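Package: rgcsim
Title: Multicompartment Conductance-Based Models of ON and OFF Retinal Ganglion Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates ON and OFF retinal ganglion cells as multicompartment
    Hodgkin-Huxley models on reconstructed or synthetic dendritic trees. Provides
    SWC morphology input/output and standardization (including the four-region
    axon with a high-density sodium-channel band), nine voltage- and
    calcium-gated membrane currents with regional channel distributions, an
    implicit cable-equation solver on the compartment tree, current-clamp
    protocols, spike-train and subthreshold analysis (CV of the inter-spike
    interval, sag, rebound bursting, subthreshold oscillations), and a
    constraint-driven search of the persistent-sodium, T-type calcium and
    h-current conductance space that classifies parameter sets into ON,
    OFF-transient and OFF-sustained phenotypes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
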