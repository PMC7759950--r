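Package: sunqtl
Title: QTL Mapping of Rubisco Activation Rate and Dynamic Photosynthesis
    Traits in Doubled-Haploid Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate the apparent Rubisco activation rate (1/tau)
    from leaf photosynthetic induction curves measured after a moderate-to-
    saturating light step, and to map quantitative trait loci (QTL) for
    dynamic and steady-state photosynthetic traits in doubled-haploid (DH)
    populations.  Gas-exchange traces are normalized to a common
    intercellular CO2 concentration, the activation rate is obtained from a
    windowed log-linear regression with an R-squared guarded window
    extension, and traits are scanned with a from-scratch Haley-Knott
    composite interval mapping engine with forward-selected cofactors and
    permutation-based genome-wide thresholds.  A synthetic-data module
    simulates DH genotypes along a genetic map (Haldane model), QTL-driven
    trait architectures, and mechanistic induction curves coupling Rubisco
    activation kinetics with stomatal dynamics, so every analysis stage can
    be exercised and validated without instrument data.  Includes an
    in-silico re-run of the chamber equilibration-time experiment comparing
    QTL detection from snapshot phenotypes at 5, 10 and 15 minutes against
    steady state.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
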