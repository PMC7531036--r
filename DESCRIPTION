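Package: eaetx
Title: Blocked Moderated-t Differential Expression and Permutation
    Gene-Set Enrichment for EAE Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for spinal-cord and T-helper-cell expression
    arrays from experimental autoimmune encephalomyelitis (EAE) studies:
    detection-based probe filtering and glog variance-stabilizing
    normalization, per-probe generalized least squares with chips or pools
    as a random block effect (consensus intra-block correlation by REML),
    empirical-Bayes moderated t-tests, directional contrast set algebra,
    a permutation gene-set overlap test against disease risk-gene lists
    with censoring-aware p-values and step-down adjustment, gene-set
    principal-component disease scoring, k-means partition-stability
    analysis, and paired exact binomial fold-change and direction tests.
    Includes a synthetic-data generator that emulates the randomized block
    study design with planted ground truth, so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    MASS
Config/testthat/edition: 3
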