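Package: dendroK
Title: Activity-Dependent Extracellular Potassium and Dendritic Integration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Models how synaptic-activity-dependent changes in extracellular
    potassium shift the potassium reversal potential in dendritic segments and
    thereby regulate dendritic integration. Provides samplers for
    orientation-tuned synapses on dendritic segments (similar vs diverse tuning
    regimes), cylinder-in-cylinder estimates of extracellular potassium
    accumulation and the resulting Nernst reversal shifts, a one-dimensional
    axial diffusion simulator with pump clearance, a conductance-based
    point-dendrite model of NMDA-dependent dendritic spikes integrated with an
    exponential Euler scheme, current-voltage fixed-point (attractor) analysis,
    a linear spike-threshold plane linking synapse count, mean synaptic
    activity and the reversal shift, and a multi-compartment fractal neuron
    model for somatic firing gain and orientation selectivity analysis.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
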