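Package: qsarga
Title: QSAR Modelling with Genetic-Algorithm Descriptor Selection and a
    Full Validation Battery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds quantitative structure-activity relationship (QSAR)
    models from SMILES and activity tables. Computes distance-constrained
    pharmacophore-pair descriptors (topological atom-pair counts, charge
    sums around a centre atom, geometric counts about the centre of mass)
    on molecular graphs typed with a configurable atom-class table, curates
    activity records to pEC50, performs objective feature selection
    (constant, near-constant and inter-correlated descriptor removal),
    selects descriptor subsets by a genetic algorithm with leave-one-out
    Q2 fitness and a breaking-point choice of model size, and validates
    ordinary-least-squares models with leave-one-out and leave-many-out
    cross-validation, external Q2F1/Q2F2/Q2F3 and concordance statistics,
    Roy rm2 and Golbraikh-Tropsha checks, Y-randomization, the QUIK rule,
    and a leverage-based applicability domain (Williams plot).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
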