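Package: vagcycle
Title: Longitudinal Dynamics of the Vaginal Ecosystem Across Childbirth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing longitudinal 16S rRNA amplicon surveys of the
    vaginal microbiota collected across pregnancy, delivery, and the postpartum
    interval. Provides rule-based community-state designation from diversity
    and top-ASV features, species-level labelling of Lactobacillus ASVs by
    alignment to type-strain references, delivery-anchored turnover and
    mixed-effects diversity trends, Kaplan-Meier and Cox analyses of postpartum
    time-to-dominance with landmarking and time-dependent covariates,
    cluster-robust subsampled logistic regression for parity effects,
    repeated-measures correlation networks linking taxa and cytokines,
    constrained correspondence analysis, and a synthetic cohort generator with
    closed-form ground truth for validating every estimator in the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    nlme,
    sandwich,
    stats,
    survival,
    utils,
    vegan
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
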