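Package: coflux
Title: Community Flux Analysis for Binary Methanotroph-Phototroph Cocultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Constraint-based metabolic modeling toolkit for predicting and
    tracking interspecies metabolic exchange in a two-species
    methanotroph-cyanobacteria coculture. Provides flux balance and flux
    variability analysis on stoichiometric models (JSON dialect and SBML L3
    input), compartmentalized community model construction with a shared
    exchange pool and configurable exchange policies, steady-state community
    optimization with abundance-scaled bounds solved by bisection, dynamic
    FBA with lexicographic objectives in a bioreactor loop, a semi-structured
    gas-liquid Monod kinetic model of the coculture, and a kinetically
    constrained dynamic community method that records the time evolution of
    cross-feeding fluxes. Includes a deterministic toy community with exact
    rational optima so all methods are testable without external data. A
    dense two-phase simplex solver is built in.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    xml2,
    yaml,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
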