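Package: netenergy
Title: Structural-Balance Energy Analysis of Signed Functional Brain Networks
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes the triangle-balance energy of signed, weighted
    functional connectivity networks and provides the full analysis
    pipeline around it: whole-brain and canonical sub-network energies,
    rest-to-task energy changes, weight-permutation null models,
    nonparametric repeated-measures inference (Friedman, pairwise
    Wilcoxon with correction, intraclass correlation across
    parcellations), comparator global graph measures, and SVM-based
    cognitive-state classification and age regression with subject-wise
    leave-one-out cross-validation. Includes a synthetic-cohort
    generator producing signed correlation matrices with controllable
    triangle imbalance, so every pipeline stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
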