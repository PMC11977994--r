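Package: targetse
Title: Genetic Evidence Enrichment for Labeled Drug Side Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether human genetic evidence for a drug
    target predicts the side effects on the drug's label. Builds ontology
    (MeSH-style) semantic similarity from information content (combined
    Lin and Resnik scores), constructs the universe of drug by side-effect
    pairs, applies genetic-insight and similar-indication confounder
    filters, and quantifies enrichment with exact Fisher odds ratios,
    threshold sensitivity sweeps, stratified Mantel-Haenszel tests,
    logistic models, predictive-value metrics and binned breakdowns.
    Includes a seeded synthetic-data generator with planted effect sizes
    so the whole pipeline is testable without proprietary source data.
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
    igraph,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
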