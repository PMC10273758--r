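# Decile risk stratification and feature importance.

#' Rank scores into deciles
#'
#' Scores are sorted in descending order (stable: ties keep input order) and
#' cut into ten groups.  With `n = 10q + r`, the top decile gets `q` members
#' and the `r` remainder members go one each to deciles 2 through `r + 1`,
#' so the top decile is never the larger one (889 scores give decile sizes
#' 88, 89, ..., 89).
#'
#' @param scores numeric vector, length >= 10.
#' @return integer decile assignment (1 = highest scores), aligned with the
#'   input.
#' @seealso [decileRiskTable()]
#' @export
rankIntoDeciles <- function(scores) {
  n <- length(scores)
  if (n < 10) stop("need at least 10 scores to form deciles")
  q <- n %/% 10L
  r <- n %% 10L
  sizes <- rep(q, 10L)
  if (r > 0) sizes[1L + seq_len(r)] <- sizes[1L + seq_len(r)] + 1L
  ord <- order(-scores, seq_along(scores))
  dec <- integer(n)
  dec[ord] <- rep(seq_len(10L), times = sizes)
  dec
}

#' Odds ratio of a decile versus the whole set
#'
#' `OR = (a / b) / (A / B)`: the case/control odds inside the decile divided
#' by the odds in the entire evaluated set ("than the average woman", with
#' the decile included in the reference).
#'
#' @param a,b case and control counts in the decile.
#' @param A,B case and control totals.
#' @return the odds ratio; `Inf` (with attribute `infinite = TRUE`) when
#'   `b = 0`.
#' @examples
#' round(oddsRatioVsOverall(75, 13, 227, 662), 1)  # 16.8
#' @export
oddsRatioVsOverall <- function(a, b, A, B) {
  stopifnot(A > 0, B > 0, a >= 0, b >= 0)
  if (b == 0) {
    out <- Inf
    attr(out, "infinite") <- TRUE
    return(out)
  }
  (a / b) / (A / B)
}

#' Woolf confidence interval for a decile odds ratio
#'
#' Normal approximation on the log odds ratio:
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/A + 1/B))`.  When any count is
#' zero the Haldane-Anscombe 0.5 correction is added to all four counts and
#' the result carries attribute `corrected = TRUE`.
#'
#' @inheritParams oddsRatioVsOverall
#' @param z normal quantile (default 1.959964, the two-sided 95% level).
#' @return named vector `c(low, high)`.
#' @examples
#' round(woolfCi(57, 32, 227, 662), 1)  # (3.3, 8.2)
#' @export
woolfCi <- function(a, b, A, B, z = 1.959964) {
  corrected <- FALSE
  if (any(c(a, b, A, B) == 0)) {
    a <- a + 0.5; b <- b + 0.5; A <- A + 0.5; B <- B + 0.5
    corrected <- TRUE
  }
  lor <- log((a / b) / (A / B))
  se <- sqrt(1 / a + 1 / b + 1 / A + 1 / B)
  out <- c(low = exp(lor - z * se), high = exp(lor + z * se))
  if (corrected) attr(out, "corrected") <- TRUE
  out
}

#' Decile risk-stratification table
#'
#' Ranks the evaluated samples by score, splits them into deciles, and
#' reports per-decile case/control counts, the odds ratio of each decile
#' against the whole set, and its 95% Woolf interval.
#'
#' @param scores risk scores of the evaluated samples.
#' @param labels 0/1 labels (1 = case); both classes must be present.
#' @return data.frame with columns `decile`, `nCases`, `nControls`,
#'   `oddsRatio`, `ciLow`, `ciHigh`; the case/control totals are stored in
#'   attributes `totalCases` and `totalControls`.
#' @export
decileRiskTable <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  A <- sum(labels == 1L)
  B <- sum(labels == 0L)
  if (A == 0L || B == 0L) stop("both classes must be present")
  dec <- rankIntoDeciles(scores)
  a <- vapply(1:10, function(d) sum(labels == 1L & dec == d), integer(1))
  b <- vapply(1:10, function(d) sum(labels == 0L & dec == d), integer(1))
  or <- numeric(10); lo <- numeric(10); hi <- numeric(10)
  for (d in 1:10) {
    or[d] <- oddsRatioVsOverall(a[d], b[d], A, B)
    ci <- woolfCi(a[d], b[d], A, B)
    lo[d] <- ci[["low"]]; hi[d] <- ci[["high"]]
  }
  out <- data.frame(decile = 1:10, nCases = a, nControls = b,
                    oddsRatio = or, ciLow = lo, ciHigh = hi)
  attr(out, "totalCases") <- A
  attr(out, "totalControls") <- B
  out
}

#' Case enrichment in the top score fraction
#'
#' @inheritParams decileRiskTable
#' @param fraction fraction of the ranked samples to keep (e.g. 0.1 for the
#'   top decile); the group holds `floor(fraction * n)` samples.
#' @return named vector `c(nCases, nTotal)`.
#' @examples
#' # 75 of the 88 top-decile members being cases is 85% enrichment
#' @export
topFraction <- function(scores, labels, fraction) {
  labels <- as.integer(labels)
  stopifnot(fraction > 0, fraction <= 1)
  n <- length(scores)
  nTop <- max(1L, floor(fraction * n))
  ord <- order(-scores, seq_len(n))
  top <- ord[seq_len(nTop)]
  c(nCases = sum(labels[top] == 1L), nTotal = nTop)
}

#' Feature importance of a fitted model
#'
#' For gradient-boosting models, per-feature mean absolute SHAP (TreeSHAP)
#' contribution, with the per-sample signed contributions kept in the
#' `contributions` attribute for plotting.  For every other family,
#' permutation importance: the mean drop in held-out-style AUC over
#' `nPermutations` seeded permutations of each feature column.
#'
#' @param model a [CSLVModel-class].
#' @param data a [LabeledCohort-class] (or samples x features matrix plus
#'   `labels`) to attribute over.
#' @param labels 0/1 labels, required when `data` is a plain matrix.
#' @param nPermutations permutations per feature (permutation mode).
#' @param seed seed for the permutations.
#' @return data.frame with columns `feature`, `importance`, `share`
#'   (importance / total importance), sorted by decreasing importance.
#'   SHAP mode carries attributes `contributions` (samples x features) and
#'   `baseValue`.
#' @export
importanceSummary <- function(model, data, labels = NULL,
                              nPermutations = 10, seed = 1L) {
  stopifnot(is(model, "CSLVModel"))
  if (is(data, "LabeledCohort")) {
    labels <- unname(cohortLabels(data))
    x <- featureMatrix(data)
  } else {
    x <- data
    stopifnot(is.matrix(x), !is.null(labels))
  }
  x <- x[, model@featureNames, drop = FALSE]
  if (identical(model@family, "gradient_boosting")) {
    contrib <- predict(model@fit, xgboost::xgb.DMatrix(x, nthread = 1),
                       predcontrib = TRUE)
    p <- ncol(x)
    base <- contrib[, p + 1L]
    contrib <- contrib[, seq_len(p), drop = FALSE]
    colnames(contrib) <- colnames(x)
    importance <- colMeans(abs(contrib))
  } else {
    baseAuc <- aucScore(predictRisk(model, x), labels)
    permSeeds <- deriveSeeds(seed, ncol(x))
    importance <- vapply(seq_len(ncol(x)), function(j) {
      drops <- withSeed(permSeeds[j], {
        vapply(seq_len(nPermutations), function(i) {
          xp <- x
          xp[, j] <- sample(xp[, j])
          baseAuc - aucScore(predictRisk(model, xp), labels)
        }, numeric(1))
      })
      mean(drops)
    }, numeric(1))
    names(importance) <- colnames(x)
  }
  total <- sum(pmax(importance, 0))
  share <- if (total > 0) pmax(importance, 0) / total
           else rep(0, length(importance))
  out <- data.frame(feature = names(importance),
                    importance = unname(importance),
                    share = unname(share),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  if (identical(model@family, "gradient_boosting")) {
    attr(out, "contributions") <- contrib
    attr(out, "baseValue") <- base
  }
  out
}
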