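Package: scansoc
Title: Social Integration Measures from Scan-Sampling Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds weighted social networks from behavioural scan-sampling
    records of group-living animals and quantifies each individual's social
    integration with two weighted-network measures: vertex strength
    centrality and the deviation from edge weight disparity. Provides the
    accompanying statistical pipeline (normal mixed models with AICc
    backward selection, Holm-Bonferroni-corrected Mann-Whitney post-hoc
    tests) for comparing rearing-background classes, plus a calibrated
    synthetic-data generator so every stage can be tested by parameter
    recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    withr,
    igraph,
    lme4,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
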