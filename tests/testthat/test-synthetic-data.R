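# Generative model of the synthetic cohorts: offsets, labels, renderings.

test_that("offset draws are deterministic and match the configured scale", {
  cfg <- tinyConfig(nCases = 2000, nControls = 8000, seed = 5,
                    chromSizes = c(`1` = 1e6), segments = 4, tau = 0.1,
                    riskSpec = RiskSpec())
  t1 <- simulateTrueOffsets(cfg)
  t2 <- simulateTrueOffsets(cfg)
  expect_identical(trueOffsets(t1), trueOffsets(t2))
  expect_equal(dim(trueOffsets(t1)), c(10000L, 4L))
  # sample SD of each segment column at n = 10,000 sits inside tight bounds
  sds <- apply(trueOffsets(t1), 2, sd)
  expect_true(all(sds > 0.097 & sds < 0.103))
  # degenerate SD: all offsets exactly zero
  z <- simulateTrueOffsets(tinyConfig(tau = 0, riskSpec = RiskSpec()))
  expect_true(all(trueOffsets(z) == 0))
})

test_that("intercept calibration hits the target prevalence", {
  # null model: closed form logit(0.25) and a flat probability field
  cfg <- tinyConfig(nCases = 100, nControls = 300, riskSpec = RiskSpec(),
                    prevalence = 0.25)
  truth <- calibrateAndAssignLabels(simulateTrueOffsets(cfg))
  expect_equal(truth@calibratedIntercept, log(1 / 3), tolerance = 1e-6)
  # any spec: mean predicted probability within 1e-6 of target
  cfg2 <- tinyConfig(nCases = 500, nControls = 1500,
                     riskSpec = RiskSpec(c("1_q0" = 15, "2_q2" = -10)),
                     prevalence = 0.2)
  truth2 <- calibrateAndAssignLabels(simulateTrueOffsets(cfg2))
  eta <- riskLinearPredictor(trueOffsets(truth2), truth2@config@riskSpec)
  expect_lt(abs(mean(plogis(truth2@calibratedIntercept + eta)) - 0.2), 1e-6)
  # strong single coefficient: case rate climbs across quintiles of its delta
  cfg3 <- tinyConfig(nCases = 1250, nControls = 3750,
                     riskSpec = RiskSpec(c("1_q0" = 20)), seed = 21)
  truth3 <- simulateCohort(cfg3)
  q <- cut(trueOffsets(truth3)[, "1_q0"], breaks = quantile(
    trueOffsets(truth3)[, "1_q0"], probs = seq(0, 1, 0.2)),
    include.lowest = TRUE, labels = FALSE)
  rates <- tapply(unname(cohortLabels(truth3)), q, mean)
  expect_true(all(diff(rates) > 0))
})

test_that("label prevalence stays within binomial bounds of the target", {
  for (seed in c(1, 2, 3)) {
    cfg <- tinyConfig(nCases = 500, nControls = 1500, seed = seed)
    truth <- simulateCohort(cfg)
    n <- length(cohortLabels(truth))
    p <- truth@config@targetPrevalence
    expect_lt(abs(mean(cohortLabels(truth)) - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("per-SNP rendering adds noise around the segment offsets", {
  # zero noise: every SNP equals its segment's offset exactly
  cfg0 <- tinyConfig(nCases = 10, nControls = 30, sigma = 0, snps = 40)
  tr0 <- simulateCohort(cfg0)
  l2r0 <- renderL2R(tr0)
  part <- partitionChromosomes(cfg0@chromSizes, 4)
  m1 <- l2rValues(l2r0[["1"]])
  expect_equal(dim(m1), c(40L, 40L))
  seg <- findInterval(snpPositions(l2r0[["1"]]),
                      GenomicRanges::start(part[as.character(
                        GenomicRanges::seqnames(part)) == "1"]))
  for (p in c(1, 17)) {
    expect_equal(unname(m1[, p]),
                 unname(trueOffsets(tr0)[p, paste0("1_q", seg - 1)]))
  }
  # CLT bound: per-segment SNP means stay within 4 sigma / sqrt(m) of delta
  cfg <- tinyConfig(nCases = 20, nControls = 60, sigma = 0.2, snps = 1000)
  tr <- simulateCohort(cfg)
  l2r <- renderL2R(tr)
  feats <- assembleFeatures(lapply(l2r, cslvFromL2R,
                                   partition = partitionChromosomes(
                                     cfg@chromSizes, 4)))
  mPerSeg <- 250
  bound <- 4 * 0.2 / sqrt(mPerSeg)
  diffs <- abs(featureMatrix(feats) -
                 trueOffsets(tr)[, colnames(featureMatrix(feats))])
  expect_lt(max(diffs), bound)
  # determinism of the rendering
  expect_identical(l2rValues(renderL2R(tr)[["2"]]), l2rValues(l2r[["2"]]))
})

test_that("segment reporting threshold suppresses near-diploid segments", {
  cfg <- tinyConfig(nCases = 500, nControls = 2000, tau = 0.05, seed = 31,
                    chromSizes = c(`1` = 4e6), riskSpec = RiskSpec())
  truth <- simulateCohort(cfg)
  # threshold 0: every (person, segment) pair is reported
  all <- renderSegmentRecords(truth, threshold = 0)
  expect_length(all, 2500 * 4)
  # threshold Inf: nothing reported
  expect_length(renderSegmentRecords(truth, threshold = Inf), 0)
  # threshold = tau: reported fraction ~ 2 * (1 - pnorm(1)) = 0.3173
  rep05 <- renderSegmentRecords(truth, threshold = 0.05)
  frac <- length(rep05) / (2500 * 4)
  p <- 2 * (1 - pnorm(1))
  expect_lt(abs(frac - p), 4 * sqrt(p * (1 - p) / (2500 * 4)))
  # reported records carry exactly the above-threshold true offsets
  expect_true(all(abs(rep05$segmentMean) >= 0.05))
  sid <- rep05$sampleId[1]
  expect_setequal(rep05$segmentMean[rep05$sampleId == sid],
                  trueOffsets(truth)[sid,
                    abs(trueOffsets(truth)[sid, ]) >= 0.05])
})

test_that("features recovered from rendered data track the true offsets", {
  # recovery condition sigma/sqrt(m) < tau/3 holds: m = 250 SNPs per
  # segment, sigma = 0.2, tau = 0.1
  cfg <- tinyConfig(nCases = 75, nControls = 225, snps = 1000,
                    tau = 0.1, sigma = 0.2)
  truth <- simulateCohort(cfg)
  l2r <- renderL2R(truth)
  part <- partitionChromosomes(cfg@chromSizes, 4)
  feats <- assembleFeatures(lapply(l2r, cslvFromL2R, partition = part))
  fm <- featureMatrix(feats)
  for (f in colnames(fm))
    expect_gt(cor(fm[, f], trueOffsets(truth)[, f]), 0.95)
})

test_that("exact-size subsampling returns the requested class counts", {
  cfg <- tinyConfig(nCases = 40, nControls = 120, seed = 13)
  truth <- simulateCohort(cfg)
  sub <- subsampleCohort(truth, nCases = 20, nControls = 50)
  expect_equal(sum(cohortLabels(sub) == 1), 20)
  expect_equal(sum(cohortLabels(sub) == 0), 50)
  expect_identical(trueOffsets(sub),
                   trueOffsets(truth)[rownames(trueOffsets(sub)), ])
  expect_error(subsampleCohort(truth, nCases = 10000),
               "too small")
})

test_that("invalid configurations are rejected", {
  expect_error(tinyConfig(prevalence = 0), "targetPrevalence")
  expect_error(tinyConfig(tau = -1), "standard deviations")
  expect_error(tinyConfig(riskSpec = RiskSpec(c("9_q0" = 1))),
               "absent from the partition")
})
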