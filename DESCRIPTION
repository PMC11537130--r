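Package: metamodtrend
Title: Longitudinal Metabolomics Module Trend Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for longitudinal untargeted metabolomics studies of
    treatment response: missingness filtering, K-nearest-neighbour imputation,
    median scaling and log transformation; weighted correlation network
    analysis with topological overlap, module detection and eigen-metabolites;
    random-intercept linear mixed models for per-metabolite and per-module
    trend testing with false discovery rate control; permutation-based
    pathway enrichment with normalized enrichment scores; composite
    disability response scoring (EDSS-Plus and the overall disability
    response score) and quality-of-life change; and logistic and partial
    Spearman association of metabolome change with clinical improvement.
    Includes a synthetic cohort generator with planted correlated modules
    and known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
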