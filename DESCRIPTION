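Package: replaynet
Title: Conditions for Replay of Neuronal Assembly Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of sequence replay in networks of neuronal
    assemblies. Provides a clocked leaky integrate-and-fire network simulator
    (excitatory-inhibitory assemblies, global inhibition, and a minimal
    excitatory-only variant) with conductance synapses, delayed spike delivery,
    inhibitory spike-timing-dependent plasticity and Poisson background drive;
    replay detection and quantification (pulse speed, width, connectivity grid
    scans); a time-discrete population model of membrane-potential
    distributions with rectangle and clipped-Gaussian shapes; closed-form
    conditions linking recurrent and feedforward connectivity to replay
    success and speed; and the mapping between spiking-network parameters and
    the population-model coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
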