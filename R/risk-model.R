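# Classifier training, stacking and repeated-split AUC evaluation.

#' Area under the ROC curve
#'
#' Mann-Whitney pair-counting estimate: the probability that a randomly
#' chosen case outscores a randomly chosen control, with ties credited 0.5.
#' Computed from midranks, so it is exact and invariant under any strictly
#' monotone transform of the scores.
#'
#' @param scores numeric risk scores.
#' @param labels 0/1 labels (1 = case); both classes must be present.
#' @return AUC in \[0, 1\].
#' @examples
#' aucScore(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))  # 1
#' @export
aucScore <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute an AUC")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve coordinates
#'
#' @inheritParams aucScore
#' @return data.frame with columns `threshold`, `fpr`, `tpr`, one row per
#'   distinct score plus the (0,0) anchor, ordered from strictest to most
#'   permissive threshold.
#' @export
rocCoordinates <- function(scores, labels) {
  labels <- as.integer(labels)
  ord <- order(-scores)
  s <- scores[ord]; l <- labels[ord]
  n1 <- sum(l == 1L); n0 <- sum(l == 0L)
  tp <- cumsum(l == 1L); fp <- cumsum(l == 0L)
  last <- !duplicated(s, fromLast = TRUE)
  data.frame(threshold = c(Inf, s[last]),
             fpr = c(0, fp[last] / n0),
             tpr = c(0, tp[last] / n1))
}

# Stratified fold assignment; refolds with a fresh derived seed (up to
# maxAttempts) if any fold ends up with a single class on either side.
.stratifiedFolds <- function(labels, k, seed, maxAttempts = 5L) {
  n <- length(labels)
  seeds <- deriveSeeds(seed, maxAttempts)
  for (a in seq_len(maxAttempts)) {
    folds <- withSeed(seeds[a], {
      f <- integer(n)
      for (cl in unique(labels)) {
        idx <- sample(which(labels == cl))
        f[idx] <- rep_len(seq_len(k), length(idx))
      }
      f
    })
    ok <- all(vapply(seq_len(k), function(f) {
      inFold <- labels[folds == f]
      outFold <- labels[folds != f]
      length(unique(inFold)) == 2L && length(unique(outFold)) == 2L
    }, logical(1)))
    if (ok) return(folds)
  }
  stop("could not build ", k, "-fold partition with both classes in every ",
       "fold after ", maxAttempts, " attempts")
}

.defaultHyperparameters <- function(family) {
  switch(family,
    gradient_boosting = list(nrounds = 100, max_depth = 3, eta = 0.1,
                             subsample = 0.8, colsample_bytree = 0.8,
                             min_child_weight = 2),
    random_forest = list(num.trees = 300, min.node.size = 5),
    feedforward_net = list(size = 32, decay = 1e-3, maxit = 200),
    logistic = list(),
    stacked_ensemble = list(foldCount = 5),
    stop("unknown model family: ", family))
}

.resolveTrainingData <- function(x, labels) {
  if (is(x, "LabeledCohort")) {
    labels <- unname(cohortLabels(x))
    x <- featureMatrix(x)
  } else if (is(x, "CSLVFeatureSet")) {
    x <- featureMatrix(x)
  }
  stopifnot(is.matrix(x), !is.null(colnames(x)))
  list(x = x, labels = as.integer(labels))
}

#' Train a risk classifier
#'
#' Fits one of five model families on a samples-by-features matrix (or a
#' [LabeledCohort-class]) and returns a [CSLVModel-class] whose
#' [predictRisk()] scores lie in \[0, 1\].  Family defaults: gradient
#' boosting (100 rounds, depth 3, eta 0.1), random forest (300 probability
#' trees), feedforward network (one hidden layer of 32 logistic units on
#' standardized inputs), plain logistic regression, and a
#' super-learner stacked ensemble (logistic meta-learner on out-of-fold base
#' predictions over 5 folds).  Deterministic families are deterministic
#' given the spec seed.
#'
#' @param x samples x features matrix, [CSLVFeatureSet-class] or
#'   [LabeledCohort-class].
#' @param labels 0/1 vector (ignored when `x` is a labeled cohort).
#' @param spec an [AlgorithmSpec-class].
#' @return a fitted [CSLVModel-class].
#' @examples
#' x <- matrix(rnorm(400), 100, 4,
#'             dimnames = list(sprintf("s%d", 1:100), sprintf("f%d", 1:4)))
#' y <- as.integer(x[, 1] + rnorm(100, sd = 0.5) > 0)
#' fit <- trainModel(x, y, AlgorithmSpec("logistic"))
#' head(predictRisk(fit, x))
#' @export
trainModel <- function(x, labels = NULL, spec) {
  stopifnot(is(spec, "AlgorithmSpec"))
  validObject(spec)
  td <- .resolveTrainingData(x, labels)
  x <- td$x; y <- td$labels
  if (length(unique(y)) < 2L)
    stop("training labels must contain both classes")
  vars <- apply(x, 2, stats::var)
  if (all(vars == 0))
    warning("all features have zero variance; the model cannot discriminate")
  hp <- utils::modifyList(.defaultHyperparameters(spec@family),
                          spec@hyperparameters)
  if (identical(spec@family, "stacked_ensemble"))
    return(.trainStack(x, y, spec, hp))
  fit <- switch(spec@family,
    gradient_boosting = .fitGbm(x, y, hp, spec@seed),
    random_forest = .fitForest(x, y, hp, spec@seed),
    feedforward_net = .fitNet(x, y, hp, spec@seed),
    logistic = .fitLogistic(x, y))
  model <- new("CSLVModel", family = spec@family, fit = fit$fit,
               featureNames = colnames(x),
               center = fit$center %||% numeric(0),
               scale = fit$scale %||% numeric(0),
               baseModels = list(), meta = NULL, seed = spec@seed)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.fitGbm <- function(x, y, hp, seed) {
  d <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  params <- list(objective = "binary:logistic", max_depth = hp$max_depth,
                 eta = hp$eta, subsample = hp$subsample,
                 colsample_bytree = hp$colsample_bytree,
                 min_child_weight = hp$min_child_weight,
                 nthread = 1, seed = seed)
  list(fit = xgboost::xgb.train(params = params, data = d,
                                nrounds = hp$nrounds, verbose = 0))
}

.fitForest <- function(x, y, hp, seed) {
  df <- as.data.frame(x)
  df$.label <- factor(y, levels = c(0L, 1L))
  list(fit = ranger::ranger(
    dependent.variable.name = ".label", data = df, probability = TRUE,
    num.trees = hp$num.trees, min.node.size = hp$min.node.size,
    seed = seed, num.threads = 1))
}

.fitNet <- function(x, y, hp, seed) {
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  fit <- withSeed(seed,
    nnet::nnet(xs, y, size = hp$size, decay = hp$decay, maxit = hp$maxit,
               entropy = TRUE, MaxNWts = 100000, trace = FALSE))
  list(fit = fit, center = center, scale = scale)
}

.fitLogistic <- function(x, y) {
  df <- as.data.frame(x)
  names(df) <- paste0("V", seq_len(ncol(x)))  # syntactic names for glm
  df$.label <- y
  fit <- suppressWarnings(
    stats::glm(.label ~ ., data = df, family = stats::binomial()))
  list(fit = fit)
}

.trainStack <- function(x, y, spec, hp) {
  baseSpecs <- lapply(seq_along(spec@baseFamilies), function(i)
    AlgorithmSpec(spec@baseFamilies[i], seed = spec@seed + i))
  oof <- oofPredictions(x, y, baseSpecs, foldCount = hp$foldCount,
                        seed = spec@seed)
  meta <- .fitLogistic(oof, y)$fit
  baseModels <- lapply(baseSpecs, function(bs) trainModel(x, y, bs))
  new("CSLVModel", family = "stacked_ensemble", fit = NULL,
      featureNames = colnames(x), center = numeric(0), scale = numeric(0),
      baseModels = baseModels, meta = meta, seed = spec@seed)
}

#' Out-of-fold base-learner predictions
#'
#' The meta-features of a super learner: for each of `foldCount` stratified
#' folds, every base family is trained on the other folds and predicts the
#' held-out fold, so no prediction is made by a model that saw that row.
#'
#' @param x samples x features matrix.
#' @param labels 0/1 vector.
#' @param baseSpecs list of [AlgorithmSpec-class] for the base families.
#' @param foldCount number of folds.
#' @param seed fold-assignment seed.
#' @return n x length(baseSpecs) matrix of out-of-fold risk scores.
#' @export
oofPredictions <- function(x, labels, baseSpecs, foldCount = 5, seed = 1L) {
  y <- as.integer(labels)
  folds <- .stratifiedFolds(y, foldCount, seed)
  oof <- matrix(NA_real_, nrow = nrow(x), ncol = length(baseSpecs))
  colnames(oof) <- vapply(baseSpecs, function(s) s@family, character(1))
  for (f in seq_len(foldCount)) {
    inFold <- folds == f
    for (b in seq_along(baseSpecs)) {
      fit <- trainModel(x[!inFold, , drop = FALSE], y[!inFold],
                        baseSpecs[[b]])
      oof[inFold, b] <- predictRisk(fit, x[inFold, , drop = FALSE])
    }
  }
  oof
}

#' Score new samples with a fitted model
#'
#' @param object a [CSLVModel-class].
#' @param newdata samples x features matrix or [CSLVFeatureSet-class];
#'   columns are aligned to the model's feature names.
#' @param ... unused.
#' @return numeric risk scores in \[0, 1\], one per row.
#' @rdname predictRisk
#' @export
setMethod("predictRisk", "CSLVModel", function(object, newdata, ...) {
  if (is(newdata, "CSLVFeatureSet")) newdata <- featureMatrix(newdata)
  stopifnot(is.matrix(newdata))
  miss <- setdiff(object@featureNames, colnames(newdata))
  if (length(miss))
    stop("newdata is missing model features: ",
         paste(utils::head(miss, 5), collapse = ", "))
  x <- newdata[, object@featureNames, drop = FALSE]
  switch(object@family,
    gradient_boosting =
      predict(object@fit, xgboost::xgb.DMatrix(x, nthread = 1)),
    random_forest = {
      p <- predict(object@fit, data = as.data.frame(x),
                   num.threads = 1)$predictions
      p[, "1"]
    },
    feedforward_net = {
      xs <- sweep(sweep(x, 2, object@center), 2, object@scale, "/")
      as.numeric(predict(object@fit, xs))
    },
    logistic = {
      df <- as.data.frame(x)
      names(df) <- paste0("V", seq_len(ncol(x)))
      as.numeric(predict(object@fit, newdata = df, type = "response"))
    },
    stacked_ensemble = {
      base <- vapply(object@baseModels, function(m) predictRisk(m, x),
                     numeric(nrow(x)))
      if (is.null(dim(base))) base <- matrix(base, nrow = nrow(x))
      df <- as.data.frame(base)
      names(df) <- paste0("V", seq_len(ncol(base)))
      as.numeric(predict(object@meta, newdata = df, type = "response"))
    },
    stop("unknown model family: ", object@family))
})

#' One-sample 95% t-interval
#'
#' `mean(x) +/- t(0.975, n-1) * sd(x) / sqrt(n)`; degenerates to a
#' zero-width interval when all values are equal.
#'
#' @param values numeric vector (n >= 2).
#' @param conf confidence level (default 0.95).
#' @return named vector `c(low, mean, high)`.
#' @export
tInterval <- function(values, conf = 0.95) {
  stopifnot(length(values) >= 2)
  m <- mean(values)
  if (stats::sd(values) == 0)
    return(c(low = m, mean = m, high = m))
  tt <- stats::t.test(values, conf.level = conf)
  c(low = tt$conf.int[1], mean = m, high = tt$conf.int[2])
}

#' Repeated-split evaluation of a classifier
#'
#' For each repeat of the plan, trains the model on the training partition
#' and computes the AUC on the held-out partition; summarizes the
#' per-repeat AUCs with their mean and a one-sample 95% t-interval, after a
#' Shapiro-Wilk normality check (a warning, not a failure, when p < 0.05).
#' Failed repeats are recorded and skipped as long as at least two succeed.
#'
#' @param dataset a [LabeledCohort-class].
#' @param spec an [AlgorithmSpec-class]; its per-repeat seed is derived from
#'   the plan seed.
#' @param plan a [SplitPlan-class] (repeats >= 2).
#' @return a [ModelEvaluation-class].
#' @export
evaluateRepeated <- function(dataset, spec, plan) {
  stopifnot(is(dataset, "LabeledCohort"), is(plan, "SplitPlan"))
  if (plan@repeats < 2L) stop("need at least 2 repeats")
  splits <- makeSplits(dataset, plan)
  x <- featureMatrix(dataset)
  y <- unname(cohortLabels(dataset))
  modelSeeds <- deriveSeeds(deriveSeeds(plan@seed, plan@repeats + 1L)[
    plan@repeats + 1L], plan@repeats)
  aucs <- rep(NA_real_, plan@repeats)
  for (r in seq_len(plan@repeats)) {
    sp <- splits[[r]]
    rspec <- spec
    rspec@seed <- modelSeeds[r]
    if (identical(rspec@family, "stacked_ensemble") &&
        is.null(rspec@hyperparameters$foldCount))
      rspec@hyperparameters$foldCount <- plan@foldCount
    aucs[r] <- tryCatch({
      fit <- trainModel(x[sp$train, , drop = FALSE], y[sp$train], rspec)
      aucScore(predictRisk(fit, x[sp$test, , drop = FALSE]), y[sp$test])
    }, error = function(e) {
      warning("repeat ", r, " failed: ", conditionMessage(e))
      NA_real_
    })
  }
  ok <- !is.na(aucs)
  if (sum(ok) < 2L)
    stop("fewer than two repeats succeeded; cannot form a t-interval")
  vals <- aucs[ok]
  ci <- tInterval(vals)
  shapiroP <- if (length(vals) >= 3 && stats::sd(vals) > 0)
    stats::shapiro.test(vals)$p.value else NA_real_
  if (!is.na(shapiroP) && shapiroP < 0.05)
    warning(sprintf(
      "per-repeat AUCs fail the Shapiro-Wilk normality check (p = %.3g); ",
      shapiroP), "interpret the t-interval with caution")
  new("ModelEvaluation", aucs = vals, meanAuc = unname(ci["mean"]),
      ciLow = unname(ci["low"]), ciHigh = unname(ci["high"]),
      shapiroP = shapiroP, foldCount = plan@foldCount,
      repeats = plan@repeats, nFailed = sum(!ok))
}
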