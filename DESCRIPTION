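Package: CSLVRisk
Title: Chromosomal-Scale Length Variation Features for Germline Cancer Risk Prediction
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes chromosomal-scale length variation (CSLV) features from
    germline SNP-array copy-number data, in both per-SNP log2-ratio matrix form
    and segmented (SEG-like) form, and evaluates their value for case/control
    cancer risk prediction. Provides a synthetic-cohort simulator with known
    ground truth, strict readers and writers for the supported file dialects,
    case/control cohort construction rules, classifier training (gradient
    boosting, random forest, feedforward network, logistic regression, and a
    cross-validated stacked ensemble), repeated-split AUC evaluation with
    t-interval confidence bounds, decile odds-ratio risk stratification with
    Woolf confidence intervals, and SHAP or permutation feature importance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    data.table,
    xgboost,
    ranger,
    nnet
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    withr
biocViews: CopyNumberVariation, Classification, SNP, RiskAssessment
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
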