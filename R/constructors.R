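#' Create a risk specification
#'
#' @param linearTerms named numeric vector of linear coefficients keyed by
#'   segment identifier (e.g. `c("3_q1" = 8)`); empty for a null model.
#' @param interactionTerms data.frame with columns `first`, `second`,
#'   `coefficient` giving pairwise product terms; may be empty.
#' @param intercept usually left `NA`; set by prevalence calibration.
#' @return a [RiskSpec-class] object.
#' @examples
#' RiskSpec(linearTerms = c("1_q0" = 10),
#'          interactionTerms = data.frame(first = "1_q0", second = "2_q1",
#'                                        coefficient = 120))
#' @export
RiskSpec <- function(linearTerms = numeric(0),
                     interactionTerms = data.frame(
                       first = character(0), second = character(0),
                       coefficient = numeric(0), stringsAsFactors = FALSE),
                     intercept = NA_real_) {
  interactionTerms$first <- as.character(interactionTerms$first)
  interactionTerms$second <- as.character(interactionTerms$second)
  interactionTerms$coefficient <- as.numeric(interactionTerms$coefficient)
  new("RiskSpec", linearTerms = linearTerms,
      interactionTerms = interactionTerms,
      intercept = as.numeric(intercept))
}

#' A risk specification with no genetic effect
#'
#' Every person gets the same case probability (the target prevalence), so any
#' classifier's true AUC is 0.5. Used for null-calibration checks.
#' @return a [RiskSpec-class] with no terms.
#' @export
nullRiskSpec <- function() RiskSpec()

#' The default strong, partly nonlinear risk specification
#'
#' Places linear effects on eight segments spread across the genome and
#' pairwise interaction effects on four segment pairs, so that risk is driven
#' by combinations of chromosomal-scale changes rather than a single locus.
#' With the default offset scale (`personSegmentSd = 0.1`) the linear part of
#' the predictor has SD about 3.4 and the interaction part about 1.5, giving a
#' cohort whose labels are strongly but not perfectly predictable.
#'
#' @param segmentsPerChromosome segment count the identifiers refer to.
#' @return a [RiskSpec-class].
#' @export
strongSignalRiskSpec <- function(segmentsPerChromosome = 4) {
  stopifnot(segmentsPerChromosome >= 1)
  q <- function(chrom, idx) paste0(chrom, "_q", idx %% segmentsPerChromosome)
  linear <- c(12, -12, 12, -12, 12, 12, -12, 12)
  names(linear) <- c(q(1, 0), q(2, 1), q(5, 2), q(8, 3),
                     q(11, 0), q(14, 1), q(17, 2), q(22, 3))
  inter <- data.frame(
    first = c(q(1, 0), q(5, 2), q(3, 1), q(9, 2)),
    second = c(q(2, 1), q(8, 3), q(12, 0), q(20, 3)),
    coefficient = c(150, -150, 150, 150),
    stringsAsFactors = FALSE
  )
  RiskSpec(linearTerms = linear, interactionTerms = inter)
}

#' Create a simulation configuration
#'
#' Defaults describe the cohort used throughout the package's own evaluation:
#' GRCh37 autosome lengths, four segments per chromosome (so segment
#' identifiers match the quarter-chromosome CSLV features), a per-person
#' segment-offset SD of 0.1 l2r units, per-SNP noise SD of 0.2, a case
#' prevalence of 0.25, and the reporting threshold 0.01 below which a
#' TCGA-style segment record is suppressed.
#'
#' @param nCases,nControls target class sizes; the simulated pool holds
#'   `nCases + nControls` persons.
#' @param chromSizes named vector of chromosome lengths in bp.
#' @param snpsPerChromosome evenly spaced SNP probes per chromosome.
#' @param segmentsPerChromosome segments per chromosome (default 4, i.e.
#'   quarter-chromosomes).
#' @param personSegmentSd SD of true per-person segment offsets (l2r units).
#' @param snpNoiseSd SD of per-SNP measurement noise (l2r units).
#' @param riskSpec a [RiskSpec-class]; default [strongSignalRiskSpec()].
#' @param targetPrevalence mean case probability after calibration.
#' @param segReportThreshold |offset| below which no segment record is
#'   emitted.
#' @param seed integer master seed.
#' @return a validated [SimulationConfig-class].
#' @examples
#' cfg <- SimulationConfig(nCases = 50, nControls = 150,
#'                         snpsPerChromosome = 100, seed = 1)
#' @export
SimulationConfig <- function(nCases = 1500,
                             nControls = 4500,
                             chromSizes = grch37ChromSizes(includeX = FALSE),
                             snpsPerChromosome = 1000,
                             segmentsPerChromosome = 4,
                             personSegmentSd = 0.1,
                             snpNoiseSd = 0.2,
                             riskSpec = strongSignalRiskSpec(segmentsPerChromosome),
                             targetPrevalence = 0.25,
                             segReportThreshold = 0.01,
                             seed = 1L) {
  cfg <- new("SimulationConfig",
    nCases = as.integer(nCases), nControls = as.integer(nControls),
    chromSizes = chromSizes,
    snpsPerChromosome = as.integer(snpsPerChromosome),
    segmentsPerChromosome = as.integer(segmentsPerChromosome),
    personSegmentSd = as.numeric(personSegmentSd),
    snpNoiseSd = as.numeric(snpNoiseSd),
    riskSpec = riskSpec,
    targetPrevalence = as.numeric(targetPrevalence),
    segReportThreshold = as.numeric(segReportThreshold),
    seed = as.integer(seed))
  segIds <- unlist(lapply(names(chromSizes), cslvFeatureNames,
                          k = cfg@segmentsPerChromosome))
  referenced <- c(names(riskSpec@linearTerms),
                  riskSpec@interactionTerms$first,
                  riskSpec@interactionTerms$second)
  missing <- setdiff(referenced, segIds)
  if (length(missing))
    stop("riskSpec references segments absent from the partition: ",
         paste(missing, collapse = ", "))
  cfg
}

#' Create a split plan
#'
#' @param repeats independent train/test repeats (default 10).
#' @param testFraction held-out fraction per repeat (default 0.15, mirroring
#'   an 889-of-5925 held-out set).
#' @param foldCount folds for cross-validated stacking (default 10).
#' @param seed integer seed; per-repeat seeds are derived from it.
#' @return a [SplitPlan-class].
#' @export
SplitPlan <- function(repeats = 10, testFraction = 0.15, foldCount = 10,
                      seed = 1L) {
  new("SplitPlan", repeats = as.integer(repeats),
      testFraction = as.numeric(testFraction),
      foldCount = as.integer(foldCount), seed = as.integer(seed))
}

#' Create an algorithm specification
#'
#' @param family model family: `"gradient_boosting"`, `"random_forest"`,
#'   `"feedforward_net"`, `"logistic"`, or `"stacked_ensemble"`.
#' @param hyperparameters named list overriding family defaults (see
#'   [trainModel()] for the defaults).
#' @param baseFamilies base families for a stacked ensemble.
#' @param seed integer seed for stochastic families.
#' @return an [AlgorithmSpec-class].
#' @examples
#' AlgorithmSpec("gradient_boosting", list(nrounds = 50))
#' AlgorithmSpec("stacked_ensemble")
#' @export
AlgorithmSpec <- function(family,
                          hyperparameters = list(),
                          baseFamilies = c("gradient_boosting",
                                           "random_forest", "logistic"),
                          seed = 1L) {
  new("AlgorithmSpec", family = family, hyperparameters = hyperparameters,
      baseFamilies = if (identical(family, "stacked_ensemble"))
        baseFamilies else character(0),
      seed = as.integer(seed))
}

#' Create a CSLV feature set
#'
#' @param features samples x features numeric matrix with sample ids as row
#'   names and feature names (`<chrom>_q<k>`) as column names.
#' @param rowData optional per-feature annotation (chromosome, segment span).
#' @param colData optional per-sample annotation.
#' @return a [CSLVFeatureSet-class] (features as rows, Bioconductor
#'   orientation).
#' @seealso [featureMatrix()] to get the samples x features view back.
#' @export
CSLVFeatureSet <- function(features, rowData = NULL, colData = NULL) {
  stopifnot(is.matrix(features))
  if (is.null(rownames(features)) || is.null(colnames(features)))
    stop("feature matrix needs sample ids as rownames and feature names as colnames")
  assay <- t(features)
  args <- list(assays = S4Vectors::SimpleList(cslv = assay))
  if (!is.null(rowData)) args$rowData <- rowData
  if (!is.null(colData)) args$colData <- colData
  se <- do.call(SummarizedExperiment::SummarizedExperiment, args)
  new("CSLVFeatureSet", se)
}

#' Attach binary labels to a feature set
#'
#' @param features a [CSLVFeatureSet-class].
#' @param labels 0/1 vector, either named by sample id or in column order.
#' @param provenance rule-set name recorded in the metadata.
#' @return a [LabeledCohort-class].
#' @export
LabeledCohort <- function(features, labels, provenance = "manual") {
  if (!is.null(names(labels))) {
    miss <- setdiff(colnames(features), names(labels))
    if (length(miss))
      stop("labels missing for samples: ", paste(miss, collapse = ", "))
    labels <- labels[colnames(features)]
  }
  colData(features)$label <- as.integer(labels)
  metadata(features)$provenance <- provenance
  new("LabeledCohort", features)
}
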