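Package: spikeforce
Title: FORCE Training of Chaotic Spiking Neural Networks
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulator and trainer for recurrent spiking neural networks
    whose linear readouts are learned online by recursive least squares
    (FORCE learning). Provides theta, leaky integrate-and-fire and
    Izhikevich neuron reservoirs plus a rate-network baseline, exponential
    synaptic filtering, chaotic static weight generation, supervisor
    signal generators (oscillators, Van der Pol, Lorenz, note sequences,
    high-dimensional temporal signals), post-training perturbations
    (excitation/inhibition rescaling, temporal compression and reversal,
    lesioning), and quantitative read-outs such as firing statistics,
    replay classification, eigenspectra, spike-deletion chaos diagnostics
    and network-size convergence experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    deSolve,
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
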