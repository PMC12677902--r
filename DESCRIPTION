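Package: hvcnet
Title: Biophysical Network Model of Sequence Propagation in the Songbird Nucleus HVC
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based (Hodgkin-Huxley) simulation of the zebra finch
    premotor nucleus HVC. Implements single-compartment models of the three
    HVC neuron classes (RA-projecting, X-projecting, and interneurons) with
    their class-specific ionic currents, AMPA and GABA-A synapse dynamics, a
    randomized chain-of-microcircuits network builder with structured
    feedback inhibition, a fixed-step network integrator with stochastic
    background current, burst detection and sequence-propagation metrics,
    and scripted perturbation and robustness experiments that probe how
    intrinsic conductances and synaptic coupling control the propagation of
    sparse sequential bursting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
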