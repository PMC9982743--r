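Package: standstruct
Title: Non-Spatial Stand Structure Analysis for Pure Pine Forests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the horizontal and vertical structure of
    even-aged pure conifer stands from plot-inventory tables: diameter-class
    binning and Shannon-Wiener structural diversity, distribution moments,
    a midrank-adjusted Anderson-Darling k-sample test with permutation
    p-values, gradient-boosted attribution of site and stand drivers of
    diameter diversity with partial-dependence summaries, TSTRAT vertical
    stratification, and Wright path analysis of crown dimensions on stem
    diameter and tree height.  Includes a seeded synthetic stand generator
    with known ground truth for validating every estimator, and a single
    orchestrating entry point that reproduces the full analysis
    deterministically.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    e1071,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
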