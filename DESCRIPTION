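Package: gtneuron
Title: Growth Transform Spiking Neuron and Population Simulator
Version: 0.1.0
Authors@R:
    person("gtneuron", "developers", email = "gtneuron@example.org",
           role = c("aut", "cre"))
Description: Simulator for energy-based spiking neural networks driven by
    Growth Transform (Baum-Eagon) multiplicative updates. Membrane potentials
    evolve under a bound-constrained network energy functional whose gradient
    discontinuity generates spikes; a library of per-neuron modulation
    functions reproduces tonic spiking, bursting, spike-frequency adaptation,
    integrator behavior and pre-synaptic/global adaptation without moving the
    network attractor. Includes kernel-coupled population geometry (rate and
    time-to-first-spike coding, binned population trajectories), a Hebbian
    spiking associative memory with trajectory-based similarity decoding and
    capacity/noisy-pattern classification experiments, seeded synthetic input
    generators, canned experiment protocols and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
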