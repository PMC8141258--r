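Package: th17translate
Title: Translational Th17 Transcriptomics: Endotype Scoring, Cross-Study
    Correlation, Cell Deconvolution and Pharmacodynamics
Version: 0.1.0
Authors@R:
    person("Pipeline", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for translational transcriptomics of the
    Th17/IL-17 axis in severe asthma and its mouse models: per-sample
    gene-signature scores with cut-off endotype clustering, pairwise
    Pearson correlation of differential-expression log-ratios across
    studies and species after FDR filtering and ortholog harmonization,
    a fold-change-ranked sliding-window weighted overlap score for
    cell-type marker lists, digital cell quantification by elastic-net
    regression on an immune-cell compendium with group averaging and
    quantity filtering, and a percent-inhibition / Hill exposure-response
    pharmacodynamic layer. Includes seeded synthetic-data generators
    emulating the statistical structure of each input so the full
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
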