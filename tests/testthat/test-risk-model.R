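# Classifiers, stacking and repeated evaluation.

test_that("pair-counting AUC agrees with ROC integration and handles ties", {
  expect_equal(aucScore(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(aucScore(rep(0.5, 20), rep(c(0, 1), 10)), 0.5)
  expect_error(aucScore(1:5, rep(1, 5)), "both classes")
  set.seed(3)
  for (i in 1:100) {
    n <- sample(20:80, 1)
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # force some ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    expect_equal(aucScore(scores, labels), trapezoidAuc(scores, labels),
                 tolerance = 1e-12)
  }
  # invariance under strictly monotone transforms
  set.seed(4)
  s <- rnorm(100); l <- rbinom(100, 1, 0.5)
  expect_equal(aucScore(plogis(3 * s - 1), l), aucScore(s, l))
  expect_equal(aucScore(rank(s), l), aucScore(s, l))
})

test_that("every model family fits, scores in [0,1] and is seeded", {
  coh <- toyCohort(n = 150, seed = 9)
  x <- featureMatrix(coh)
  y <- unname(cohortLabels(coh))
  for (fam in c("gradient_boosting", "random_forest", "feedforward_net",
                "logistic")) {
    fit <- trainModel(x, y, AlgorithmSpec(fam, seed = 2))
    p <- predictRisk(fit, x)
    expect_true(all(p >= 0 & p <= 1), info = fam)
    fit2 <- trainModel(x, y, AlgorithmSpec(fam, seed = 2))
    expect_equal(predictRisk(fit2, x), p, info = fam)
    # column order of newdata must not matter
    expect_equal(predictRisk(fit, x[, rev(colnames(x))]), p, info = fam)
  }
  # a single perfectly separating feature yields training AUC 1
  xs <- cbind(sep = c(rep(1, 30), rep(-1, 30)),
              noise = rnorm(60))
  rownames(xs) <- sprintf("s%d", 1:60)
  ys <- rep(c(1L, 0L), each = 30)
  sepFit <- trainModel(xs, ys, AlgorithmSpec("logistic"))
  expect_equal(aucScore(predictRisk(sepFit, xs), ys), 1)
  # degenerate features warn but do not fail
  xz <- matrix(0, 40, 2, dimnames = list(sprintf("s%d", 1:40), c("a", "b")))
  expect_warning(trainModel(xz, rep(c(0L, 1L), 20),
                            AlgorithmSpec("logistic")), "zero variance")
  expect_error(trainModel(xs, rep(1L, 60), AlgorithmSpec("logistic")),
               "both classes")
})

test_that("shuffled labels leave the cross-validated AUC at chance", {
  coh <- toyCohort(n = 300, seed = 17)
  lab <- unname(cohortLabels(coh))
  shuffled <- withr::with_seed(5, sample(lab))
  null <- LabeledCohort(CSLVFeatureSet(featureMatrix(coh)), shuffled,
                        provenance = "permuted")
  ev <- evaluateRepeated(null, AlgorithmSpec("logistic"),
                         SplitPlan(repeats = 20, seed = 6))
  expect_lte(ev@ciLow, 0.5)
  expect_gte(ev@ciHigh, 0.5)
})

test_that("out-of-fold meta-features match a hand-rolled fold computation", {
  coh <- toyCohort(n = 20, seed = 23)
  x <- featureMatrix(coh)
  y <- unname(cohortLabels(coh))
  baseSpecs <- list(AlgorithmSpec("logistic"),
                    AlgorithmSpec("gradient_boosting", seed = 3))
  oof <- oofPredictions(x, y, baseSpecs, foldCount = 2, seed = 31)
  expect_equal(dim(oof), c(20L, 2L))
  expect_false(anyNA(oof))
  # brute force: recompute each half's predictions from the other half
  folds <- CSLVRisk:::.stratifiedFolds(y, 2, 31)
  for (f in 1:2) {
    for (b in 1:2) {
      fit <- trainModel(x[folds != f, ], y[folds != f], baseSpecs[[b]])
      expect_equal(unname(oof[folds == f, b]),
                   unname(predictRisk(fit, x[folds == f, , drop = FALSE])))
    }
  }
})

test_that("identical base learners make a rank-identical ensemble", {
  coh <- toyCohort(n = 120, seed = 29)
  spec <- AlgorithmSpec("stacked_ensemble",
                        baseFamilies = c("logistic", "logistic"), seed = 8)
  ens <- trainModel(coh, spec = spec)
  x <- featureMatrix(coh)
  base <- predictRisk(ens@baseModels[[1]], x)
  expect_equal(cor(predictRisk(ens, x), base, method = "spearman"), 1)
})

test_that("the stacked ensemble meta-learner never sees in-fold predictions", {
  # an intentionally leaky variant (meta-learner trained on in-sample base
  # predictions) must look better on train and no better on test
  coh <- toyCohort(n = 400, seed = 37, beta = 8)
  splits <- makeSplits(coh, SplitPlan(repeats = 2, testFraction = 0.25,
                                      seed = 41))[[1]]
  x <- featureMatrix(coh)
  y <- unname(cohortLabels(coh))
  xtr <- x[splits$train, ]; ytr <- y[splits$train]
  xte <- x[splits$test, ]; yte <- y[splits$test]
  baseFams <- c("gradient_boosting", "random_forest")
  proper <- trainModel(xtr, ytr,
                       AlgorithmSpec("stacked_ensemble",
                                     baseFamilies = baseFams, seed = 13))
  # leaky variant built from the proper ensemble's own (overfit) base models
  inFold <- vapply(proper@baseModels, function(m) predictRisk(m, xtr),
                   numeric(nrow(xtr)))
  leakyMeta <- suppressWarnings(glm(ytr ~ ., family = binomial(),
                                    data = as.data.frame(inFold)))
  leaky <- proper
  leaky@meta <- leakyMeta
  # the leaky meta-learner sees near-perfect in-fold base predictions, so
  # its apparent (training) discrimination is inflated ...
  expect_gt(aucScore(fitted(leakyMeta), ytr),
            aucScore(fitted(proper@meta), ytr))
  # ... but it buys nothing on held-out data
  testProper <- aucScore(predictRisk(proper, xte), yte)
  testLeaky <- aucScore(predictRisk(leaky, xte), yte)
  expect_lte(testLeaky, testProper + 0.02)
})

test_that("the t-interval matches the closed form and repeats are seeded", {
  vals <- c(0.81, 0.83, 0.79, 0.84, 0.80, 0.82, 0.85, 0.78, 0.83, 0.81)
  ci <- tInterval(vals)
  oracle <- closedFormT(vals)
  expect_equal(unname(ci[c("low", "high")]), oracle, tolerance = 1e-12)
  expect_equal(unname(tInterval(rep(0.7, 5))), c(0.7, 0.7, 0.7))
  coh <- toyCohort(n = 150, seed = 43)
  plan <- SplitPlan(repeats = 5, seed = 19)
  ev1 <- evaluateRepeated(coh, AlgorithmSpec("gradient_boosting"), plan)
  ev2 <- evaluateRepeated(coh, AlgorithmSpec("gradient_boosting"), plan)
  expect_identical(ev1@aucs, ev2@aucs)
  expect_true(ev1@ciLow <= ev1@meanAuc && ev1@meanAuc <= ev1@ciHigh)
})
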