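Package: phellopt
Title: Response-Surface Modelling and Gene-Set Genetic-Algorithm
    Optimization of Phellinus Fermentation Conditions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for optimizing submerged-fermentation culture conditions
    for flavonoid production by the medicinal fungus Phellinus. Fits a
    second-order response surface (linear, squared and pairwise-interaction
    terms in seven culture factors) to one-factor-at-a-time experiment
    records by ordinary least squares with partial-F stepwise term
    selection, and maximizes the fitted surface over the feasible factor
    box with a gene-set genetic algorithm in which binary chromosome
    segments encode individual factors and mutation replaces whole
    segments. Ships the 45-run Phellinus flavonoid dataset, a frozen
    published yield equation, a closed-form box-constrained maximizer used
    as an optimization oracle, and a synthetic-surface simulator for
    parameter-recovery and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
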