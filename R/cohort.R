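# Case/control cohort construction and repeated train/test splitting.

.checkCoverage <- function(features, phenotypes) {
  miss <- setdiff(colnames(features), phenotypes$sample_id)
  if (length(miss))
    stop("phenotypes missing for ", length(miss), " feature sample(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  # germline features only: age (or any non-CSLV covariate) must never be a
  # feature column
  if (any(tolower(rownames(features)) %in% c("age", "age_years")))
    stop("age must not appear among the features")
  phenotypes[match(colnames(features), phenotypes$sample_id), ]
}

.finishCohort <- function(features, isCase, isControl, provenance) {
  if (!any(isCase)) stop("cohort has zero cases")
  if (!any(isControl)) stop("cohort has zero controls")
  keep <- isCase | isControl
  message(provenance, " cohort: ", sum(isCase), " cases, ",
          sum(isControl), " controls (", sum(!keep), " samples dropped)")
  sub <- features[, keep]
  LabeledCohort(sub, labels = as.integer(isCase[keep]),
                provenance = provenance)
}

#' Build a biobank-style case/control cohort
#'
#' Cases are women flagged as breast cancer by *both* self report and the
#' cancer registry; controls are women with no cancer record of any kind
#' (neither flag set, no cancer type).  Everyone else — men, women with a
#' non-breast cancer, women flagged by only one source — is dropped.
#'
#' @param features a [CSLVFeatureSet-class].
#' @param phenotypes data.frame from [readPhenotypes()] covering every
#'   feature sample.
#' @return a [LabeledCohort-class] with provenance `"ukb"`.
#' @seealso [buildTcgaCohort()]
#' @export
buildUkbCohort <- function(features, phenotypes) {
  ph <- .checkCoverage(features, phenotypes)
  female <- ph$sex == "F"
  isCase <- female & ph$self_report_cancer & ph$registry_cancer &
    ph$cancer_type == "breast"
  isControl <- female & !ph$self_report_cancer & !ph$registry_cancer &
    ph$cancer_type == ""
  .finishCohort(features, isCase, isControl, "ukb")
}

#' Build a tumor-atlas-style case/control cohort
#'
#' Cases are women with a breast cancer diagnosis; controls are women with
#' any *other* cancer diagnosis (in a cancer atlas every participant has
#' some cancer).  Men and women without a recorded cancer type are dropped.
#'
#' @inheritParams buildUkbCohort
#' @return a [LabeledCohort-class] with provenance `"tcga"`.
#' @export
buildTcgaCohort <- function(features, phenotypes) {
  ph <- .checkCoverage(features, phenotypes)
  female <- ph$sex == "F"
  isCase <- female & ph$cancer_type == "breast"
  isControl <- female & !ph$cancer_type %in% c("", "breast")
  .finishCohort(features, isCase, isControl, "tcga")
}

# Allocate a stratified test set: round(testFraction * n) samples total,
# spread over classes by largest-remainder so test prevalence stays within
# one sample of the overall prevalence.
.testAllocation <- function(labels, testFraction) {
  n <- length(labels)
  nTest <- round(testFraction * n)
  classes <- sort(unique(labels))
  nc <- vapply(classes, function(cl) sum(labels == cl), integer(1))
  raw <- nc * nTest / n
  base <- floor(raw)
  rem <- nTest - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, nc, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), classes)
}

#' Generate repeated stratified train/test splits
#'
#' Each repeat holds out `testFraction` of the samples, stratified by label
#' so the test prevalence matches the overall prevalence to within one
#' sample.  Per-repeat seeds are derived reproducibly from the plan seed, so
#' the full sequence is deterministic.
#'
#' @param dataset a [LabeledCohort-class].
#' @param plan a [SplitPlan-class].
#' @return list of length `repeats`; each element has integer index vectors
#'   `train` and `test` (disjoint, covering all samples).
#' @export
makeSplits <- function(dataset, plan) {
  stopifnot(is(dataset, "LabeledCohort"), is(plan, "SplitPlan"))
  validObject(plan)
  labels <- cohortLabels(dataset)
  n <- length(labels)
  alloc <- .testAllocation(labels, plan@testFraction)
  if (any(alloc == 0L))
    stop("test partition would contain a single class; ",
         "increase testFraction or cohort size")
  if (any(alloc >= table(labels)[names(alloc)]))
    stop("training partition would contain a single class")
  seeds <- deriveSeeds(plan@seed, plan@repeats)
  lapply(seq_len(plan@repeats), function(r) {
    test <- withSeed(seeds[r], {
      unlist(lapply(names(alloc), function(cl) {
        idx <- which(labels == as.integer(cl))
        sample(idx, alloc[[cl]])
      }))
    })
    test <- sort(test)
    list(train = setdiff(seq_len(n), test), test = test)
  })
}
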