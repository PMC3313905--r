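Package: gcresist
Title: Two-Channel Microarray Pipeline for Classifying Glucocorticoid
    Resistance as Intrinsic or Acquired
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete analysis pipeline for two-channel cDNA microarray
    studies of glucocorticoid response in leukemic cells. Implements robust
    loess-based background correction under a multiplicative noise model,
    geometric-mean replicate averaging, iterative interquartile-range outlier
    exclusion, intensity-dependent (M-A) loess normalization, loop-design
    consistency filtering, cross-platform integration via one-to-one reporter
    mapping and median rank score normalization, sliding-window Z-score
    differential-expression calling, restarted k-means clustering with
    silhouette-based selection of the number of clusters, parent-child-union
    Gene Ontology overrepresentation analysis, chromosome-level expression
    aggregation, and a rule engine that classifies gene sets as reflecting
    inherent or acquired resistance from their functional-category
    enrichments. A synthetic-data generator with known ground truth makes
    every stage testable without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
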