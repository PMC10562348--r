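Package: luxnet
Title: Stochastic Lattice Model of Quorum-Sensing Colonies with a
    Resistor-Network Bioluminescence Readout
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the growth of a bacterial colony on a square lattice in
    which cells carry a fictitious charge that mediates a long-range Coulomb-like
    interaction, exchange autoinducer signals through stochastically opened
    nearest-neighbour channels, and reproduce, migrate and die according to
    simple compartmental rules.  The evolving colony is read out as a random
    resistor network whose channel resistances follow a Hill response of the
    local charges; the two-terminal current between ideal contacts serves as a
    bioluminescence analogue.  Includes observables (stationarity onset,
    oscillation frequency, power-law exponents), a power-law mapping from the
    asymptotic current to relative bioluminescence with additive per-autoinducer
    cooperative weights for Vibrio harveyi mutant panels, and constrained
    least-squares fitting of those weights to observed mutant panels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
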