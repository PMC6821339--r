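Package: gisel
Title: Genomic Index Selection with Desired Gains for Multi-Objective Breeding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating multi-objective breeding scenarios with
    desired-gains selection indices. Given genetic (G) and phenotypic (P)
    variance-covariance matrices and a vector of desired genetic gains on a
    subset of traits, the package computes restricted index weights, implied
    relative economic values, correlated responses for all traits, the index
    standard deviation and the required truncation-selection intensity and
    selected fraction, and monetizes trait changes as dry-biomass equivalents
    per hectare. A synthetic-data module generates valid G/P matrices and
    clonally replicated populations emulating a 16-trait Miscanthus sinensis
    panel, so predicted responses can be validated by Monte-Carlo truncation
    selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
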