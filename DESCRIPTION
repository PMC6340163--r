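Package: atriasim
Title: Timed-Automata Simulation of the Right Atrium and Heart-Rhythm
    Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the human right atrium as a stochastic square
    lattice of three-state timed automata: a self-exciting sinoatrial
    node (SAN) drives excitation waves across atrial cells toward a
    passive atrioventricular node (AVN) whose simultaneous-firing events
    define the heartbeat series.  Cells may stochastically refuse an
    enabled firing transition (tissue fatigue) and lattice connection
    densities model collagen deposition.  The package classifies limit
    rhythms (normal, SAN re-entry arrhythmia, lost beats, dead), sweeps
    phase diagrams over connectivity and refusal probability, measures
    wavefront propagation delay, drives the refusal probability through
    a bounded random walk to emulate non-stationary rhythms, and
    analyses RR-interval series (simulated or Holter-derived) through
    editing rules and joint probability matrices of consecutive RR
    increments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
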