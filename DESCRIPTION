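Package: triadfit
Title: Strategy Analysis and Psychological-Space Recovery for Triad
    Classification Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing restricted-classification ("odd one out")
    triad experiments with two-dimensional stimuli such as Munsell colors
    varying in chroma and brightness.  Implements deterministic response
    models (unidimensional, overall-similarity, identity, and response-bias
    strategies), participant- and block-level best-fit strategy
    classification with tie handling, non-metric multidimensional scaling
    under Euclidean and city-block configuration metrics with Procrustes
    alignment to the design space, Bayes factors for contingency tables
    (Gunel-Dickey), two-sample designs (JZS) and replication tests
    (normal-prior), power computations, and a seeded synthetic-data
    generator that emulates the blocked triad design and pairwise
    similarity-rating studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vegan,
    jsonlite
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
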