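Package: laminapipe
Title: Laminar Distribution Statistics, Spatially Adjusted Permutation
    ANOVA and Gene-Set Overlap Tests for Cortical Development Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analyses for mouse cortical-development studies:
    20-bin laminar cell-distribution profiles with depth densities and
    cumulative distributions, permutation tests for medians, the k-sample
    Anderson-Darling test, a spatially adjusted two-way ANOVA for bin
    profiles (Moran's I autocorrelation gate on residuals, maximum-likelihood
    spatial lag filtering, permutation F tests, Bonferroni post hoc),
    gene-set overlap enrichment with binomial, hypergeometric and resampling
    p-values under Benjamini-Hochberg control, thresholded Pearson
    co-expression networks with degree centrality, and dendritic-spine
    turnover rates.  Includes seeded synthetic-data generators that emulate
    the statistical structure of each input so every stage is testable
    without external data, plus file readers/writers and a pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr
Config/testthat/edition: 3
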