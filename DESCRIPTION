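Package: lineagestats
Title: Cell Lineage Statistics: Fitness Landscapes, Selection Strength and
    Cumulant Expansion of Population Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Retrospective and chronological statistics for single-cell lineage
    trees and mother-machine style isolated lineages. Estimates fitness
    landscapes for lineage traits, Kullback-Leibler and Jeffreys selection
    strength measures, the cumulant-generating-function expansion of the
    population growth rate, and the response of growth rate to fitness
    perturbations such as probabilistic cell removal. Includes a
    branching-process simulator with gamma-distributed, optionally
    mother-daughter-correlated generation times, bootstrap resampling schemes
    for uncertainty estimation, and deterministic fixture generators so every
    estimator can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'simulate.R'
    'distributions.R'
    'resample.R'
    'selection.R'
    'cgf.R'
    'analyze.R'
    'fixtures.R'
    'lineagestats-package.R'
    'treeio.R'
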