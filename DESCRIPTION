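Package: evaging
Title: Ageing Trajectories of Small RNA Cargo in Plasma Extracellular-Vesicle and Free-Circulating Fractions
Version: 0.1.0
Authors@R: person("evaging", "maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for ageing-associated small non-coding RNA cargo
    measured in two plasma fractions (extracellular-vesicle bound and free
    circulating): reads-per-million normalization and expression filtering,
    per-feature linear (Pearson) and nonlinear (distance) age-correlation
    statistics with a smoothing-spline nonlinearity screen, cross-fraction
    quadrant concordance against a uniform 25 percent null, a permutation test
    for mean correlation shifts, a constrained non-negative matrix
    factorization age-group classifier, hierarchical feature clustering with a
    fractional dendrogram cut, principal-variance-component attribution of
    expression variance, running-sum miRNA set enrichment with permutation
    nulls, miRNA-target network concordance, and delta-delta-Ct qPCR
    quantification. Ships a seeded synthetic-cohort generator emulating the
    study design so every stage is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
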