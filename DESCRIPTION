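Package: pamror
Title: Intrinsic Subtype Classification and Risk-of-Recurrence Scoring
    for Breast Cancer Expression Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A trainable implementation of the PAM50-style breast cancer
    intrinsic subtype classifier and Risk-of-Recurrence (ROR) score for
    digital gene-expression count data. Provides normalization of raw
    counts against control probes and housekeeping genes, training of the
    four prototypical subtype centroids by hierarchical clustering with
    Monte-Carlo cluster-significance testing, single-sample nearest
    centroid subtype assignment by Pearson correlation, a ridge-penalized
    Cox proportional-hazards ROR model combining subtype correlations
    with a proliferation score and binary tumor size, 0-100 score scaling
    with node-negative risk groups, and a survival-analysis evaluation
    suite (Harrell's concordance index with bootstrap comparison, subtype
    hazard ratios, Kaplan-Meier curves, intraclass correlation). A
    synthetic-data generator produces subtype-structured count data with
    control probes and proportional-hazards outcomes so the whole
    pipeline can be exercised without access to clinical cohorts.
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
    Rcpp,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
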