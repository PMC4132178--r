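Package: dupsim
Title: Forward-Time Simulation of Segmental Duplications Under Gene Conversion and Crossover
Version: 0.1.0
Authors@R:
    person("dupsim", "developers", email = "dupsim@example.org", role = c("aut", "cre"))
Description: Forward-time Wright-Fisher simulator of a two-copy segmental
    duplication evolving neutrally under mutation, interlocus gene conversion
    (IGC), and crossover. Chromosomes carry two or three blocks of L sites
    represented as sparse sets of derived-mutation positions; simulations run
    through a burn-in phase, a structured phase in which the duplication fixes
    along a conditioned neutral trajectory, and a concerted-evolution phase.
    Crossover junctions can be restricted to the single-copy block (SCC), the
    whole region (WRC), or predefined hotspots (HSC). The package computes
    nucleotide variation within and between duplicate blocks (pi_w, pi_b,
    pi_s), site-frequency spectra, binned diversity, and windowed linkage
    disequilibrium (|D'|, r^2) matrices, and ships preset experiments,
    configuration I/O, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
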