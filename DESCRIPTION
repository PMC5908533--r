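Package: wavepatch
Title: Waves and Patches in Balanced Spiking Circuits on a Lattice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of a spatially extended, balanced
    excitatory/inhibitory network of conductance-based leaky integrate-and-fire
    neurons on a periodic two-dimensional lattice with distance-dependent
    coupling. Weak localized stimuli evoke propagating wave patterns while
    strong stimuli evoke localized activity patches; the package simulates the
    circuit (Euler integration with an Rcpp core), detects and tracks
    population activity patterns, computes spike-triggered local field
    potentials and their exponential space constants, membrane-potential and
    synaptic-conductance distribution statistics (skewness, distance to
    threshold), firing rates, and raw and mean-matched Fano factors, and ships
    seeded synthetic fixture generators (moving and stationary blobs, Poisson
    and rate-switching spike fields) so every analysis is testable against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    yaml,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
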