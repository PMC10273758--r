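#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom GenomicRanges GRanges seqnames start end width mcols mcols<-
#'   start<- end<-
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   colData<- rowData rowData<-
NULL

#' Risk specification for the synthetic label model
#'
#' A `RiskSpec` describes the (possibly nonlinear) function that maps a
#' person's true per-segment copy-number offsets to their probability of being
#' a case.  The linear predictor is
#' \deqn{\eta_p = c + \sum_s \beta_s \delta_{ps} +
#'   \sum_{(s,t)} \gamma_{st} \delta_{ps}\delta_{pt}}
#' and case probabilities are `plogis(eta)`.  The intercept `c` is never set by
#' the user; it is calibrated by [calibrateAndAssignLabels()] so the mean case
#' probability matches a target prevalence.
#'
#' @slot linearTerms named numeric vector; names are segment identifiers
#'   (e.g. `"8_q2"`), values are coefficients on the raw offsets (l2r units).
#' @slot interactionTerms data.frame with columns `first`, `second`
#'   (segment identifiers) and `coefficient`; each row contributes
#'   `coefficient * delta[first] * delta[second]`.
#' @slot intercept numeric(1); `NA` until calibrated.
#'
#' @seealso [RiskSpec()], [strongSignalRiskSpec()], [nullRiskSpec()]
#' @export
setClass("RiskSpec",
  representation(
    linearTerms = "numeric",
    interactionTerms = "data.frame",
    intercept = "numeric"
  ),
  prototype(
    linearTerms = numeric(0),
    interactionTerms = data.frame(
      first = character(0), second = character(0),
      coefficient = numeric(0), stringsAsFactors = FALSE
    ),
    intercept = NA_real_
  )
)

setValidity("RiskSpec", function(object) {
  msg <- character(0)
  lt <- object@linearTerms
  if (length(lt) && (is.null(names(lt)) || any(!nzchar(names(lt)))))
    msg <- c(msg, "linearTerms must be a named numeric vector")
  it <- object@interactionTerms
  if (!all(c("first", "second", "coefficient") %in% colnames(it)))
    msg <- c(msg, "interactionTerms needs columns first, second, coefficient")
  if (length(object@intercept) != 1L)
    msg <- c(msg, "intercept must be a single number (possibly NA)")
  if (length(msg)) msg else TRUE
})

#' Configuration of a synthetic SNP-array cohort
#'
#' Holds every parameter of the generative model: cohort size, the chromosome
#' partition the true offsets live on, SNP density, the two noise scales
#' (between-person segment offsets and per-SNP measurement noise), the label
#' model, the target case prevalence, the reporting threshold that emulates
#' segmented pipelines leaving normal (diploid) regions unrecorded, and the
#' seed that makes every downstream draw reproducible.
#'
#' @slot nCases,nControls target class sizes used by [subsampleCohort()];
#'   the simulated pool has `nCases + nControls` persons.
#' @slot chromSizes named numeric vector of chromosome lengths in bp.
#' @slot snpsPerChromosome number of evenly spaced SNP probes per chromosome.
#' @slot segmentsPerChromosome number of equal-width segments (quarters by
#'   default) each chromosome is divided into; the true offsets are constant
#'   within a segment.
#' @slot personSegmentSd SD (l2r units) of the true per-person, per-segment
#'   copy-number offsets.
#' @slot snpNoiseSd SD (l2r units) of independent per-SNP measurement noise.
#' @slot riskSpec a [RiskSpec-class] describing the label model.
#' @slot targetPrevalence desired mean case probability, in (0, 1).
#' @slot segReportThreshold segments with |offset| below this are left
#'   unrecorded by [renderSegmentRecords()], mimicking segmentation pipelines
#'   that do not report normal regions.
#' @slot seed integer master seed.
#'
#' @seealso [SimulationConfig()]
#' @export
setClass("SimulationConfig",
  representation(
    nCases = "integer",
    nControls = "integer",
    chromSizes = "numeric",
    snpsPerChromosome = "integer",
    segmentsPerChromosome = "integer",
    personSegmentSd = "numeric",
    snpNoiseSd = "numeric",
    riskSpec = "RiskSpec",
    targetPrevalence = "numeric",
    segReportThreshold = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  if (object@nCases < 1L || object@nControls < 1L)
    msg <- c(msg, "nCases and nControls must be >= 1")
  cs <- object@chromSizes
  if (!length(cs) || is.null(names(cs)) || any(!nzchar(names(cs))))
    msg <- c(msg, "chromSizes must be a non-empty named vector")
  if (any(cs <= 0)) msg <- c(msg, "chromosome lengths must be > 0")
  if (anyDuplicated(names(cs))) msg <- c(msg, "duplicate chromosome names")
  if (object@snpsPerChromosome < 1L)
    msg <- c(msg, "snpsPerChromosome must be >= 1")
  if (object@segmentsPerChromosome < 1L)
    msg <- c(msg, "segmentsPerChromosome must be >= 1")
  if (object@personSegmentSd < 0 || object@snpNoiseSd < 0)
    msg <- c(msg, "standard deviations must be >= 0")
  tp <- object@targetPrevalence
  if (!(tp > 0 && tp < 1)) msg <- c(msg, "targetPrevalence must be in (0, 1)")
  if (object@segReportThreshold < 0)
    msg <- c(msg, "segReportThreshold must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated cohort
#'
#' @slot trueOffsets persons x segments matrix of true per-segment offsets
#'   (l2r units); column names are segment identifiers, row names sample ids.
#' @slot labels integer vector of 0/1 labels, or length 0 before
#'   [calibrateAndAssignLabels()] has run.
#' @slot calibratedIntercept the intercept found by prevalence calibration
#'   (`NA` before calibration).
#' @slot config the [SimulationConfig-class] that produced the cohort.
#' @export
setClass("GroundTruth",
  representation(
    trueOffsets = "matrix",
    labels = "integer",
    calibratedIntercept = "numeric",
    config = "SimulationConfig"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character(0)
  if (length(object@labels) &&
      length(object@labels) != nrow(object@trueOffsets))
    msg <- c(msg, "labels length must match the number of persons")
  if (length(object@labels) && !all(object@labels %in% c(0L, 1L)))
    msg <- c(msg, "labels must be 0/1")
  if (length(msg)) msg else TRUE
})

#' Per-SNP log2-ratio matrix for one chromosome
#'
#' The per-SNP representation of germline copy number: each row is a genomic
#' position on one chromosome, each column a sample, and each value the log2
#' ratio of measured intensity to the two-copy expectation (0 = diploid).
#'
#' @slot chromosome chromosome name (normalized, no "chr" prefix).
#' @slot positions strictly increasing 1-based bp coordinates, one per row.
#' @slot sampleIds unique sample identifiers, one per column.
#' @slot values numeric matrix, positions x samples; `NA` marks missing probes.
#' @export
setClass("L2RMatrix",
  representation(
    chromosome = "character",
    positions = "numeric",
    sampleIds = "character",
    values = "matrix"
  )
)

setValidity("L2RMatrix", function(object) {
  msg <- character(0)
  if (length(object@chromosome) != 1L)
    msg <- c(msg, "chromosome must be a single name")
  p <- object@positions
  if (length(p) && any(diff(p) <= 0))
    msg <- c(msg, "positions must be strictly increasing")
  if (anyDuplicated(object@sampleIds))
    msg <- c(msg, "sample ids must be unique")
  if (nrow(object@values) != length(p))
    msg <- c(msg, "row count must equal number of positions")
  if (ncol(object@values) != length(object@sampleIds))
    msg <- c(msg, "column count must equal number of samples")
  if (length(msg)) msg else TRUE
})

#' Samples-by-features CSLV table as a SummarizedExperiment
#'
#' Rows are CSLV features (one per chromosome segment, named
#' `<chrom>_q<index>` with a 0-based segment index), columns are samples, and
#' the single `"cslv"` assay holds the segment-mean l2r values.  `rowData`
#' carries the segment coordinates when the table was built from a partition.
#'
#' @seealso [CSLVFeatureSet()], [featureMatrix()], [assembleFeatures()]
#' @export
setClass("CSLVFeatureSet", contains = "SummarizedExperiment")

setValidity("CSLVFeatureSet", function(object) {
  msg <- character(0)
  if (!"cslv" %in% names(assays(object)))
    msg <- c(msg, "needs a 'cslv' assay")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate feature names")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample ids")
  if (length(msg)) msg else TRUE
})

#' A labeled case/control cohort
#'
#' A [CSLVFeatureSet-class] whose `colData` carries a binary `label` column
#' (1 = case) and whose metadata records the rule set (`provenance`) that
#' produced it.  Phenotype columns other than the label are never joined into
#' the feature matrix, so downstream models see CSLV features only.
#'
#' @seealso [buildUkbCohort()], [buildTcgaCohort()], [cohortLabels()]
#' @export
setClass("LabeledCohort", contains = "CSLVFeatureSet")

setValidity("LabeledCohort", function(object) {
  msg <- character(0)
  cd <- colData(object)
  if (!"label" %in% colnames(cd)) {
    msg <- c(msg, "colData must contain a 'label' column")
  } else {
    lab <- cd$label
    if (any(is.na(lab)) || !all(lab %in% c(0L, 1L)))
      msg <- c(msg, "labels must be 0/1 with no missing values")
  }
  if (is.null(metadata(object)$provenance))
    msg <- c(msg, "metadata must record a 'provenance' rule-set name")
  if (length(msg)) msg else TRUE
})

#' Repeated train/test split plan
#'
#' @slot repeats number of independent repeats (default 10).
#' @slot testFraction fraction of samples held out per repeat (default 0.15).
#' @slot foldCount folds used for cross-validated stacking (default 10).
#' @slot seed integer; per-repeat seeds are derived from it reproducibly.
#' @seealso [SplitPlan()], [makeSplits()], [evaluateRepeated()]
#' @export
setClass("SplitPlan",
  representation(
    repeats = "integer",
    testFraction = "numeric",
    foldCount = "integer",
    seed = "integer"
  )
)

setValidity("SplitPlan", function(object) {
  msg <- character(0)
  if (object@repeats < 2L) msg <- c(msg, "repeats must be >= 2")
  tf <- object@testFraction
  if (!(tf > 0 && tf < 1)) msg <- c(msg, "testFraction must be in (0, 1)")
  if (object@foldCount < 2L) msg <- c(msg, "foldCount must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Classifier family and hyperparameters
#'
#' @slot family one of `"gradient_boosting"`, `"random_forest"`,
#'   `"feedforward_net"`, `"logistic"`, `"stacked_ensemble"`.
#' @slot hyperparameters named list overriding the family defaults.
#' @slot baseFamilies for stacked ensembles, the (>= 2) base families.
#' @slot seed integer seed for stochastic families.
#' @seealso [AlgorithmSpec()], [trainModel()]
#' @export
setClass("AlgorithmSpec",
  representation(
    family = "character",
    hyperparameters = "list",
    baseFamilies = "character",
    seed = "integer"
  )
)

.MODEL_FAMILIES <- c(
  "gradient_boosting", "random_forest", "feedforward_net",
  "logistic", "stacked_ensemble"
)

setValidity("AlgorithmSpec", function(object) {
  msg <- character(0)
  if (length(object@family) != 1L || !object@family %in% .MODEL_FAMILIES)
    msg <- c(msg, paste("family must be one of:",
                        paste(.MODEL_FAMILIES, collapse = ", ")))
  if (identical(object@family, "stacked_ensemble")) {
    bf <- object@baseFamilies
    if (length(bf) < 2L)
      msg <- c(msg, "a stacked ensemble needs >= 2 base families")
    if (!all(bf %in% setdiff(.MODEL_FAMILIES, "stacked_ensemble")))
      msg <- c(msg, "base families must be non-ensemble families")
  }
  if (length(msg)) msg else TRUE
})

#' A fitted risk scorer
#'
#' Wraps a fitted classifier together with the feature names it was trained
#' on, its input standardization, and (for stacked ensembles) the base models
#' and the logistic meta-learner.  Use [predictRisk()] to obtain scores in
#' \[0, 1\].
#' @slot family the model family (see [AlgorithmSpec-class]).
#' @slot fit the underlying fitted object (family-specific).
#' @slot featureNames feature names in training order.
#' @slot center,scale per-feature standardization used by the feedforward net
#'   (empty for other families).
#' @slot baseModels list of base [CSLVModel-class] objects (ensembles only).
#' @slot meta logistic meta-learner (ensembles only).
#' @slot seed seed the model was trained with.
#' @export
setClass("CSLVModel",
  representation(
    family = "character",
    fit = "ANY",
    featureNames = "character",
    center = "numeric",
    scale = "numeric",
    baseModels = "list",
    meta = "ANY",
    seed = "integer"
  )
)

#' Repeated-split evaluation of a classifier
#'
#' @slot aucs per-repeat held-out AUCs.
#' @slot meanAuc mean of the per-repeat AUCs.
#' @slot ciLow,ciHigh 95% one-sample t-interval on the per-repeat AUCs.
#' @slot shapiroP Shapiro-Wilk normality p-value of the AUCs (`NA` when the
#'   AUCs are constant).
#' @slot foldCount,repeats the plan actually used.
#' @slot nFailed number of repeats that failed and were skipped.
#' @seealso [evaluateRepeated()]
#' @export
setClass("ModelEvaluation",
  representation(
    aucs = "numeric",
    meanAuc = "numeric",
    ciLow = "numeric",
    ciHigh = "numeric",
    shapiroP = "numeric",
    foldCount = "integer",
    repeats = "integer",
    nFailed = "integer"
  )
)

setValidity("ModelEvaluation", function(object) {
  msg <- character(0)
  if (any(object@aucs < 0 | object@aucs > 1))
    msg <- c(msg, "AUCs must lie in [0, 1]")
  if (!is.na(object@meanAuc) &&
      (object@ciLow > object@meanAuc || object@meanAuc > object@ciHigh))
    msg <- c(msg, "need ciLow <= meanAuc <= ciHigh")
  if (length(msg)) msg else TRUE
})
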