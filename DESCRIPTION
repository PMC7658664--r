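Package: cofba
Title: Community Flux Balance Analysis for Syngas-Fermenting Co-Cultures
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to build and interrogate compartmentalized multi-species
    constraint-based metabolic models of syngas-fermenting co-cultures, such as
    an acetogen paired with a chain elongator. Provides a constraint-based
    model data structure with SBML Level 3 Version 1 and tabular readers and
    writers, merging of single-species models into a community model with a
    shared extracellular compartment and explicit cross-feeding routes,
    cell-geometry-based estimation of species biomass fractions, conversion of
    chemostat measurements into volume-scaled flux constraints, flux balance
    analysis, flux variability analysis, hit-and-run flux sampling and
    infeasibility diagnosis on a built-in bounded-variable simplex solver,
    OptKnock- and RobustKnock-style bi-level knockout design with candidate
    filtering, and electron- and carbon-yield accounting. Includes generators
    for small, elementally balanced toy models of an acetogen and a chain
    elongator so the entire pipeline is testable without external model files.
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
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
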