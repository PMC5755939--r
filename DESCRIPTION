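Package: lcneuro
Title: Conductance-Based Model of CO2/H+-Sensitive Locus Coeruleus Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulator for a single-compartment, conductance-based model of a
    CO2/H+-sensitive locus coeruleus neuron. Twelve membrane currents with
    Hodgkin-Huxley gating kinetics, Hill-equation chemosensitivity scaling of
    conductances by CO2 level and intra-/extracellular pH, intracellular
    calcium shell dynamics with buffering and pump extrusion driving SK and
    BK potassium currents, piecewise-constant stimulus protocols integrated
    with a stiff variable-step solver, and spike-train analysis (threshold,
    afterhyperpolarization, amplitude, firing rates, spike-frequency
    adaptation, postinhibitory rebound, sensitivity indices, spiking-onset
    scans).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
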