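Package: costex
Title: Cost-Benefit Modelling of Gene Expression and Post-WGD Ohnolog Retention
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements a cost-benefit (COSTEX-style) model of gene-expression
    fitness in which the optimal expression level of a gene reflects a trade-off
    between an increasing benefit function and a Monod-type resource cost.
    Derives selection coefficients against expression halving (ohnolog loss),
    pseudogenization and missense mutations, couples them to a
    fixation-probability-scaled loss hazard to simulate stochastic gene
    retention after whole-genome duplications, and provides the downstream
    analysis pipeline: expression summarization, quantile normalization,
    fixed-interval retention binning, extreme-decile comparison, stratified and
    functional-category analyses, ohnolog expression-divergence metrics, and
    heterozygous knock-out fitness binning. A seeded synthetic-data generator
    emulates the statistical structure of ciliate microarray/ohnologon data so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
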