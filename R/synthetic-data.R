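# Synthetic SNP-array cohorts with known ground truth.
#
# Generative model: each person p carries a true offset delta[p, s] ~
# N(0, personSegmentSd) for every chromosome segment s, constant along the
# segment. The per-SNP representation adds N(0, snpNoiseSd) measurement noise
# at every probe; the segmented representation reports (span, delta) records,
# suppressing segments with |delta| below a reporting threshold the way
# segmentation pipelines leave normal diploid regions unrecorded. Case labels
# are Bernoulli draws from a logistic model on the true offsets whose
# intercept is calibrated to a target prevalence.

segmentPartition <- function(config) {
  partitionChromosomes(config@chromSizes, config@segmentsPerChromosome,
                       includeX = "X" %in% normalizeChromName(names(config@chromSizes)))
}

#' Draw true per-person segment offsets
#'
#' Offsets are independent draws from `N(0, personSegmentSd)` for every
#' (person, segment) pair; the result is fully determined by the
#' configuration seed.
#'
#' @param config a [SimulationConfig-class].
#' @return a [GroundTruth-class] with offsets filled in and labels unset.
#' @seealso [calibrateAndAssignLabels()], [simulateCohort()]
#' @export
simulateTrueOffsets <- function(config) {
  validObject(config)
  n <- config@nCases + config@nControls
  spans <- segmentPartition(config)
  segIds <- spans$featureName
  seeds <- deriveSeeds(config@seed, 4)
  offsets <- withSeed(seeds[1], {
    matrix(stats::rnorm(n * length(segIds), sd = config@personSegmentSd),
           nrow = n, ncol = length(segIds),
           dimnames = list(sprintf("P%06d", seq_len(n)), segIds))
  })
  new("GroundTruth", trueOffsets = offsets, labels = integer(0),
      calibratedIntercept = NA_real_, config = config)
}

#' Linear predictor of the risk model
#'
#' Evaluates `sum(beta_s * delta_s) + sum(gamma_st * delta_s * delta_t)`
#' (no intercept) for every person.
#'
#' @param offsets persons x segments matrix with segment-id column names.
#' @param riskSpec a [RiskSpec-class].
#' @return numeric vector, one value per person.
#' @export
riskLinearPredictor <- function(offsets, riskSpec) {
  eta <- numeric(nrow(offsets))
  lt <- riskSpec@linearTerms
  if (length(lt)) {
    miss <- setdiff(names(lt), colnames(offsets))
    if (length(miss))
      stop("risk spec references unknown segments: ",
           paste(miss, collapse = ", "))
    eta <- eta + drop(offsets[, names(lt), drop = FALSE] %*% lt)
  }
  it <- riskSpec@interactionTerms
  if (nrow(it)) {
    miss <- setdiff(c(it$first, it$second), colnames(offsets))
    if (length(miss))
      stop("risk spec references unknown segments: ",
           paste(miss, collapse = ", "))
    for (i in seq_len(nrow(it)))
      eta <- eta + it$coefficient[i] *
        offsets[, it$first[i]] * offsets[, it$second[i]]
  }
  eta
}

#' Calibrate the intercept and draw case/control labels
#'
#' Finds the intercept for which the mean of `plogis(intercept + eta)` over
#' the cohort equals `targetPrevalence` (to within 1e-6, by root finding on
#' the monotone mean-probability curve), then draws labels as independent
#' Bernoulli variables with those probabilities, using a seed derived from
#' the configuration seed.
#'
#' @param truth a [GroundTruth-class] with offsets present.
#' @param riskSpec label model; defaults to the configuration's.
#' @param targetPrevalence target mean case probability; defaults to the
#'   configuration's.
#' @return the [GroundTruth-class] with `labels` and `calibratedIntercept`
#'   set and the calibrated intercept stored in its risk spec.
#' @export
calibrateAndAssignLabels <- function(truth,
                                     riskSpec = truth@config@riskSpec,
                                     targetPrevalence =
                                       truth@config@targetPrevalence) {
  stopifnot(is(truth, "GroundTruth"))
  if (!nrow(truth@trueOffsets)) stop("offsets are not present")
  if (!(targetPrevalence > 0 && targetPrevalence < 1))
    stop("targetPrevalence must be in (0, 1)")
  eta <- riskLinearPredictor(truth@trueOffsets, riskSpec)
  f <- function(c0) mean(stats::plogis(c0 + eta)) - targetPrevalence
  lo <- -60; hi <- 60
  if (f(lo) > 0 || f(hi) < 0)
    stop("calibration error: could not bracket the intercept in [-60, 60]")
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  if (abs(f(root)) > 1e-6)
    stop("calibration error: residual prevalence gap above 1e-6")
  p <- stats::plogis(root + eta)
  seeds <- deriveSeeds(truth@config@seed, 4)
  labels <- withSeed(seeds[2],
                     as.integer(stats::rbinom(length(p), 1L, p)))
  truth@labels <- labels
  truth@calibratedIntercept <- root
  truth@config@riskSpec <- riskSpec
  truth@config@riskSpec@intercept <- root
  validObject(truth)
  truth
}

#' Simulate a labeled cohort in one call
#'
#' [simulateTrueOffsets()] followed by [calibrateAndAssignLabels()].
#' @param config a [SimulationConfig-class].
#' @return a labeled [GroundTruth-class].
#' @export
simulateCohort <- function(config) {
  calibrateAndAssignLabels(simulateTrueOffsets(config))
}

#' Subsample a labeled cohort to exact class sizes
#'
#' Draws exactly `nCases` cases and `nControls` controls (seeded from the
#' configuration) from a labeled cohort; errors if either class is too small.
#'
#' @param truth a labeled [GroundTruth-class].
#' @param nCases,nControls target sizes; default from the configuration.
#' @return a [GroundTruth-class] restricted to the sampled persons.
#' @export
subsampleCohort <- function(truth, nCases = truth@config@nCases,
                            nControls = truth@config@nControls) {
  stopifnot(is(truth, "GroundTruth"))
  if (!length(truth@labels)) stop("labels have not been assigned yet")
  cases <- which(truth@labels == 1L)
  controls <- which(truth@labels == 0L)
  if (length(cases) < nCases || length(controls) < nControls)
    stop("cohort too small to subsample ", nCases, " cases and ",
         nControls, " controls (have ", length(cases), " / ",
         length(controls), ")")
  seeds <- deriveSeeds(truth@config@seed, 4)
  keep <- withSeed(seeds[4], {
    sort(c(sample(cases, nCases), sample(controls, nControls)))
  })
  truth@trueOffsets <- truth@trueOffsets[keep, , drop = FALSE]
  truth@labels <- truth@labels[keep]
  truth
}

#' Render the per-SNP log2-ratio representation
#'
#' Places `snpsPerChromosome` evenly spaced 1-based probes on each
#' chromosome; each probe reports its segment's true offset plus independent
#' `N(0, snpNoiseSd)` noise.
#'
#' @param truth a labeled [GroundTruth-class].
#' @return named list of [L2RMatrix-class], one per chromosome.
#' @seealso [writeL2R()], [cslvFromL2R()]
#' @export
renderL2R <- function(truth) {
  stopifnot(is(truth, "GroundTruth"))
  if (!length(truth@labels)) stop("labels have not been assigned yet")
  config <- truth@config
  spans <- segmentPartition(config)
  n <- nrow(truth@trueOffsets)
  m <- config@snpsPerChromosome
  seeds <- deriveSeeds(config@seed, 4)
  chroms <- unique(as.character(seqnames(spans)))
  chromSeeds <- deriveSeeds(seeds[3], length(chroms))
  out <- vector("list", length(chroms))
  names(out) <- chroms
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    L <- GenomeInfoDb::seqlengths(spans)[[ch]]
    if (m > L) stop("more SNPs than base pairs on chromosome ", ch)
    pos <- floor((seq_len(m) - 1) * L / m) + 1
    sp <- spans[as.character(seqnames(spans)) == ch]
    sp <- sp[order(start(sp))]
    segOfSnp <- findInterval(pos, start(sp))
    base <- t(truth@trueOffsets[, sp$featureName[segOfSnp], drop = FALSE])
    noise <- withSeed(chromSeeds[ci],
                      matrix(stats::rnorm(m * n, sd = config@snpNoiseSd),
                             nrow = m, ncol = n))
    vals <- unname(base) + noise
    out[[ch]] <- new("L2RMatrix", chromosome = ch, positions = as.numeric(pos),
                     sampleIds = rownames(truth@trueOffsets), values = vals)
  }
  out
}

#' Render the segmented (SEG-style) representation
#'
#' Emits one record per (person, segment) whose |offset| reaches the
#' reporting threshold, carrying the segment span, the number of probes the
#' per-SNP rendering would place in it, and the offset as the segment mean.
#' Segments below the threshold produce no record, mirroring pipelines that
#' leave normal regions unrecorded.
#'
#' @param truth a labeled [GroundTruth-class].
#' @param threshold reporting threshold; defaults to the configuration's.
#' @return a `GRanges` with metadata columns `sampleId`, `numProbes`,
#'   `segmentMean`, ordered by sample then genomic position.
#' @seealso [writeSeg()], [cslvFromSegments()]
#' @export
renderSegmentRecords <- function(truth,
                                 threshold =
                                   truth@config@segReportThreshold) {
  stopifnot(is(truth, "GroundTruth"))
  if (!length(truth@labels)) stop("labels have not been assigned yet")
  config <- truth@config
  spans <- segmentPartition(config)
  spans <- spans[match(colnames(truth@trueOffsets), spans$featureName)]
  m <- config@snpsPerChromosome
  lens <- GenomeInfoDb::seqlengths(spans)
  probesBySpan <- vapply(seq_along(spans), function(i) {
    ch <- as.character(seqnames(spans))[i]
    pos <- floor((seq_len(m) - 1) * lens[[ch]] / m) + 1
    sum(pos >= start(spans)[i] & pos <= end(spans)[i])
  }, integer(1))
  hit <- which(abs(truth@trueOffsets) >= threshold, arr.ind = TRUE)
  if (!nrow(hit)) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(sampleId = character(0),
                           numProbes = integer(0),
                           segmentMean = numeric(0))
    return(gr)
  }
  ord <- order(hit[, "row"], hit[, "col"])
  hit <- hit[ord, , drop = FALSE]
  gr <- GRanges(
    seqnames = as.character(seqnames(spans))[hit[, "col"]],
    ranges = IRanges(start = start(spans)[hit[, "col"]],
                     end = end(spans)[hit[, "col"]]),
    sampleId = rownames(truth@trueOffsets)[hit[, "row"]],
    numProbes = probesBySpan[hit[, "col"]],
    segmentMean = truth@trueOffsets[hit])
  GenomeInfoDb::seqlengths(gr) <- lens[GenomeInfoDb::seqlevels(gr)]
  gr
}

#' Render a phenotype table consistent with the simulated labels
#'
#' In the `"ukb"` style, cases are women flagged by both self report and the
#' cancer registry with cancer type `"breast"`, and controls are women with
#' no cancer record at all.  In the `"tcga"` style every person is a woman
#' with a cancer diagnosis: cases have type `"breast"`, controls cycle
#' through other cancer types.
#'
#' @param truth a labeled [GroundTruth-class].
#' @param style `"ukb"` or `"tcga"`.
#' @return data.frame with columns `sample_id`, `sex`, `self_report_cancer`,
#'   `registry_cancer`, `cancer_type`.
#' @seealso [buildUkbCohort()], [buildTcgaCohort()]
#' @export
renderPhenotypes <- function(truth, style = c("ukb", "tcga")) {
  style <- match.arg(style)
  stopifnot(is(truth, "GroundTruth"))
  if (!length(truth@labels)) stop("labels have not been assigned yet")
  lab <- truth@labels
  ids <- rownames(truth@trueOffsets)
  if (style == "ukb") {
    data.frame(
      sample_id = ids, sex = "F",
      self_report_cancer = lab == 1L,
      registry_cancer = lab == 1L,
      cancer_type = ifelse(lab == 1L, "breast", ""),
      stringsAsFactors = FALSE)
  } else {
    others <- c("lung", "colon", "ovary", "melanoma", "kidney")
    data.frame(
      sample_id = ids, sex = "F",
      self_report_cancer = TRUE,
      registry_cancer = TRUE,
      cancer_type = ifelse(lab == 1L, "breast",
                           others[(seq_along(ids) %% length(others)) + 1L]),
      stringsAsFactors = FALSE)
  }
}
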