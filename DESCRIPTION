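Package: onoffrf
Title: Developmental Plasticity of ON/OFF Receptive Fields in Auditory Cortex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a rate-based feedforward model of a primary auditory
    cortex neuron receiving plastic excitatory and inhibitory ON and OFF
    inputs across tonotopic frequency channels. Hebbian plasticity with
    multiplicative synaptic noise and L1 weight normalisation, together with
    a rate-based inhibitory rule, drives the developmental divergence of ON
    and OFF receptive fields under naturalistic on/off sound sequences.
    Includes probing of model frequency response areas and
    frequency-modulated sweep direction selectivity, population statistics,
    the corresponding in vivo spike-train analysis procedures (FRA
    smoothing, characteristic frequency, bandwidth, overlap, direction
    selectivity index, DSI regression with proportional reduction of
    error), and a synthetic spiking-unit generator for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
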