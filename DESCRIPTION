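Package: sevmark
Title: Multimodal Plasma Small Extracellular Vesicle Biomarker Workflow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for liquid-biopsy biomarker discovery from plasma small
    extracellular vesicles (sEVs). Provides nanoparticle tracking style
    size-distribution summaries and group comparisons; ATR-FTIR/Raman spectral
    preprocessing (truncation, extended multiplicative signal correction,
    silent-region removal, min-max normalization) and a replicate-aware
    partial-least-squares ensemble classifier with hierarchical consensus
    voting; per-cohort differential abundance/expression with detection and
    contaminant filters and Benjamini-Hochberg tiers; cross-cohort fold-change
    concordance and reversed-pattern triage; and a harmonized machine-learning
    signature stage (per-cohort z-scoring, recursive feature elimination,
    random forest / k-nearest-neighbour / gradient-boosting model selection
    with a label-shuffle chance control). Includes a synthetic multi-cohort
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    cluster,
    class,
    randomForest,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mixOmics
Config/testthat/edition: 3
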