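# Accessors and show methods.

#' Samples-by-features matrix view
#'
#' Returns the CSLV values with samples as rows and features as columns, the
#' orientation classifiers consume.
#' @param x a [CSLVFeatureSet-class].
#' @return numeric matrix, samples x features.
#' @rdname featureMatrix
#' @export
setMethod("featureMatrix", "CSLVFeatureSet", function(x) {
  t(assay(x, "cslv"))
})

#' Sample identifiers
#'
#' @param x a [CSLVFeatureSet-class], [L2RMatrix-class] or
#'   [GroundTruth-class].
#' @return character vector of sample ids.
#' @rdname sampleIds
#' @export
setMethod("sampleIds", "CSLVFeatureSet", function(x) colnames(x))

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "L2RMatrix", function(x) x@sampleIds)

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "GroundTruth", function(x) rownames(x@trueOffsets))

#' Binary cohort labels
#'
#' @param x a [LabeledCohort-class] or labeled [GroundTruth-class].
#' @return integer 0/1 vector named by sample id (1 = case).
#' @rdname cohortLabels
#' @export
setMethod("cohortLabels", "LabeledCohort", function(x) {
  stats::setNames(colData(x)$label, colnames(x))
})

#' @rdname cohortLabels
#' @export
setMethod("cohortLabels", "GroundTruth", function(x) {
  if (!length(x@labels)) stop("labels have not been assigned yet")
  stats::setNames(x@labels, rownames(x@trueOffsets))
})

#' True per-segment offsets of a simulated cohort
#'
#' @param x a [GroundTruth-class].
#' @return persons x segments numeric matrix.
#' @rdname trueOffsets
#' @export
setMethod("trueOffsets", "GroundTruth", function(x) x@trueOffsets)

#' Positions of an l2r matrix
#' @param x an [L2RMatrix-class].
#' @return 1-based bp positions.
#' @export
snpPositions <- function(x) {
  stopifnot(is(x, "L2RMatrix"))
  x@positions
}

#' Values of an l2r matrix
#' @param x an [L2RMatrix-class].
#' @return positions x samples numeric matrix.
#' @export
l2rValues <- function(x) {
  stopifnot(is(x, "L2RMatrix"))
  x@values
}

#' Chromosome of an l2r matrix
#' @param x an [L2RMatrix-class].
#' @return chromosome name.
#' @export
chromosomeName <- function(x) {
  stopifnot(is(x, "L2RMatrix"))
  x@chromosome
}

setMethod("show", "RiskSpec", function(object) {
  cat("RiskSpec:", length(object@linearTerms), "linear term(s),",
      nrow(object@interactionTerms), "interaction term(s); intercept =",
      format(object@intercept, digits = 4), "\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n",
      " persons: ", object@nCases + object@nControls,
      " (target ", object@nCases, " cases / ", object@nControls,
      " controls)\n",
      " chromosomes: ", length(object@chromSizes),
      ", segments per chromosome: ", object@segmentsPerChromosome,
      ", SNPs per chromosome: ", object@snpsPerChromosome, "\n",
      " personSegmentSd: ", object@personSegmentSd,
      ", snpNoiseSd: ", object@snpNoiseSd,
      ", target prevalence: ", object@targetPrevalence, "\n",
      " seg report threshold: ", object@segReportThreshold,
      ", seed: ", object@seed, "\n", sep = "")
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@trueOffsets), "persons x",
      ncol(object@trueOffsets), "segments;",
      if (length(object@labels))
        paste0(sum(object@labels), " cases / ",
               sum(object@labels == 0L), " controls")
      else "labels unset", "\n")
})

setMethod("show", "L2RMatrix", function(object) {
  cat("L2RMatrix chromosome ", object@chromosome, ": ",
      length(object@positions), " SNPs x ", length(object@sampleIds),
      " samples\n", sep = "")
})

setMethod("show", "CSLVFeatureSet", function(object) {
  cat(class(object), ": ", ncol(object), " samples x ", nrow(object),
      " CSLV features\n", sep = "")
  if (is(object, "LabeledCohort")) {
    lab <- colData(object)$label
    cat("  labels: ", sum(lab == 1L), " cases / ", sum(lab == 0L),
        " controls (", metadata(object)$provenance, " rules)\n", sep = "")
  }
})

setMethod("show", "SplitPlan", function(object) {
  cat("SplitPlan:", object@repeats, "repeats, test fraction",
      object@testFraction, ",", object@foldCount, "folds, seed",
      object@seed, "\n")
})

setMethod("show", "AlgorithmSpec", function(object) {
  cat("AlgorithmSpec:", object@family)
  if (length(object@baseFamilies))
    cat(" [", paste(object@baseFamilies, collapse = " + "), "]")
  cat(", seed", object@seed, "\n")
})

setMethod("show", "CSLVModel", function(object) {
  cat("CSLVModel:", object@family, "on", length(object@featureNames),
      "features\n")
})

setMethod("show", "ModelEvaluation", function(object) {
  cat(sprintf(
    "ModelEvaluation: mean AUC %.3f, 95%% CI (%.3f, %.3f) over %d repeats\n",
    object@meanAuc, object@ciLow, object@ciHigh, length(object@aucs)))
  if (!is.na(object@shapiroP))
    cat(sprintf("  Shapiro-Wilk normality p = %.3f\n", object@shapiroP))
  if (object@nFailed > 0L)
    cat("  failed repeats:", object@nFailed, "\n")
})
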