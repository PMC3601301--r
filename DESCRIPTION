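Package: casnet
Title: Center-Annular-Surround Spiking Network Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates large two-dimensional networks of conductance-based
    Izhikevich spiking neurons wired with a center-annular-surround (CAS)
    connectivity motif: local Gaussian excitation and annular lateral
    inhibition. Synapses carry AMPA, NMDA (with magnesium block), GABA-A,
    GABA-B and a slow hyperpolarizing receptor, short-term
    depression/facilitation, spike-timing-dependent plasticity (STDP) with an
    eligibility trace, and homeostatic synaptic scaling. The package provides
    the connectivity generators (local Gaussian, annular, uniform random,
    topographically limited), a millisecond-resolution simulation engine in
    C++, population-activity metrics (Willmore-Tolhurst sparseness, a
    winner-take-all peak-rate measure, dynamical-state classification,
    orientation tuning and map smoothness, joint-position error), and three
    ready-made experiments: a coupling-strength sweep mapping winner-take-all
    regimes across architectures, orientation-map self-organization under an
    annealed inhibition ramp, and visuomotor map learning evaluated with a
    simulated two-joint arm and population-vector decoding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
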