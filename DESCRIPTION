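Package: psomcs
Title: Particle Swarm Design of Constrained Minimal Cut Sets in
    Metabolic Networks
Version: 0.1.0
Authors@R:
    person("psomcs", "maintainers", email = "psomcs@example.org",
           role = c("aut", "cre"))
Description: Computes growth-coupled strain designs for constraint-based
    metabolic models.  Constrained minimal cut sets (cMCS) are obtained
    directly from a Farkas-type dual of the stoichiometric system as a
    mixed-integer linear program that minimizes knockout support, and a
    particle swarm with constriction dynamics searches the space of
    design thresholds (e.g. guaranteed minimal product yield at nonzero
    growth) for the best achievable design.  Includes network reduction
    and compression, flux balance and flux variability analysis on a
    built-in exact simplex solver, production envelopes, brute-force
    oracles for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    xml2,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
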