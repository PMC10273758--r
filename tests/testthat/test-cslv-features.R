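# CSLV feature computation: partitioning, per-SNP and segment aggregation.

test_that("equal-width partitioning honors counts and the remainder rule", {
  expect_length(partitionChromosomes(grch37ChromSizes(), k = 4), 88)
  expect_length(partitionChromosomes(grch37ChromSizes(), k = 1,
                                     includeX = TRUE), 23)
  p <- partitionChromosomes(c(`1` = 10), k = 4)
  expect_equal(GenomicRanges::width(p), c(3, 3, 2, 2))
  expect_equal(sum(GenomicRanges::width(p)), 10)
  expect_equal(GenomicRanges::start(p), c(1, 4, 7, 9))
  expect_equal(p$featureName, c("1_q0", "1_q1", "1_q2", "1_q3"))
  expect_error(partitionChromosomes(c(`1` = 10), k = 1, includeX = TRUE),
               "unknown chromosome")
})

test_that("per-SNP features are the mean l2r over each span", {
  part <- partitionChromosomes(c(`5` = 100), k = 2)
  mk <- function(vals, pos = seq_len(nrow(vals))) {
    new("L2RMatrix", chromosome = "5", positions = as.numeric(pos),
        sampleIds = sprintf("s%d", seq_len(ncol(vals))), values = vals)
  }
  # all-zero l2r: nominal average length everywhere
  z <- mk(matrix(0, nrow = 10, ncol = 3), pos = seq(1, 100, length.out = 10))
  expect_true(all(featureMatrix(cslvFromL2R(z, part)) == 0))
  # two SNPs in one span: plain two-point mean
  m <- mk(matrix(c(0.1, 0.3), ncol = 1), pos = c(10, 20))
  expect_equal(unname(featureMatrix(cslvFromL2R(m, part))[1, ]), c(0.2, 0))
  # missing values excluded, not imputed
  m2 <- mk(matrix(c(0.1, NA, 0.5, 0.2, 0.4, NA), ncol = 2), pos = c(5, 30, 80))
  fm2 <- featureMatrix(cslvFromL2R(m2, part))
  expect_equal(unname(fm2[, "5_q0"]), c(0.1, 0.3))
  expect_equal(unname(fm2[, "5_q1"]), c(0.5, 0))
  # brute-force per-span mean on a random 200-SNP matrix
  set.seed(8)
  vals <- matrix(rnorm(200 * 4), nrow = 200)
  pos <- sort(sample(1:100000, 200))
  part2 <- partitionChromosomes(c(`5` = 100000), k = 5)
  fm <- featureMatrix(cslvFromL2R(mk(vals, pos), part2))
  for (s in seq_along(part2)) {
    inSpan <- pos >= GenomicRanges::start(part2)[s] &
      pos <= GenomicRanges::end(part2)[s]
    expected <- if (any(inSpan)) colMeans(vals[inSpan, , drop = FALSE])
                else rep(0, 4)
    expect_equal(unname(fm[, s]), unname(expected), tolerance = 1e-12)
  }
  # k = 1 reduces to the plain chromosome-wide mean
  part1 <- partitionChromosomes(c(`5` = 100000), k = 1)
  expect_equal(unname(featureMatrix(cslvFromL2R(mk(vals, pos), part1))[, 1]),
               unname(colMeans(vals)), tolerance = 1e-12)
  # linearity: scaling l2r scales every feature
  expect_equal(featureMatrix(cslvFromL2R(mk(vals * 2.5, pos), part2)),
               fm * 2.5, tolerance = 1e-12)
})

segDf <- function(sample, start, end, mean, chrom = "1") {
  GenomicRanges::GRanges(seqnames = chrom,
                         ranges = IRanges::IRanges(start = start, end = end),
                         sampleId = sample, segmentMean = mean)
}

test_that("segment aggregation is the coverage-weighted mean with diploid gaps", {
  # single long record over a whole-chromosome span: hand-computed weight
  part <- partitionChromosomes(c(`1` = 249e6), k = 1)
  gr <- segDf("s1", 1, 244e6, 0.5)
  f <- featureMatrix(cslvFromSegments(gr, part))
  expect_equal(unname(f[1, 1]), 0.5 * 244 / 249, tolerance = 1e-12)
  # a sample with no records sits at the gap value
  f2 <- featureMatrix(cslvFromSegments(gr, part, samples = c("s1", "s2")))
  expect_equal(unname(f2["s2", 1]), 0)
  # per-bp brute force on a 10 kb toy chromosome, overlaps included
  set.seed(14)
  part3 <- partitionChromosomes(c(`1` = 10000), k = 4)
  for (rep in 1:5) {
    starts <- sample(1:9500, 12)
    ends <- pmin(starts + sample(50:3000, 12, replace = TRUE), 10000)
    means <- round(rnorm(12, sd = 0.4), 3)
    gr3 <- segDf("s1", starts, ends, means)
    fm3 <- featureMatrix(cslvFromSegments(gr3, part3))
    df <- data.frame(start = starts, end = ends, mean = means)
    for (s in seq_along(part3)) {
      oracle <- perBpSpanMean(df, GenomicRanges::start(part3)[s],
                              GenomicRanges::end(part3)[s])
      expect_equal(unname(fm3[1, s]), oracle, tolerance = 1e-9)
    }
  }
  # permuting disjoint records never changes the result
  gr4 <- segDf("s1", c(1, 3001, 7001), c(3000, 7000, 10000),
               c(0.2, -0.4, 0.1))
  expect_equal(featureMatrix(cslvFromSegments(gr4, part3)),
               featureMatrix(cslvFromSegments(gr4[c(3, 1, 2)], part3)))
  # conservation: complete non-overlapping coverage at k = 1 equals the
  # length-weighted mean of the segment means
  part1 <- partitionChromosomes(c(`1` = 10000), k = 1)
  expect_equal(unname(featureMatrix(cslvFromSegments(gr4, part1))[1, 1]),
               sum(c(3000, 4000, 3000) * c(0.2, -0.4, 0.1)) / 10000,
               tolerance = 1e-12)
  # records beyond the chromosome end are clipped with a warning
  expect_warning(cslvFromSegments(segDf("s1", 9000, 12000, 1), part3),
                 "clipping")
})

test_that("the longest-overlap policy reports the dominant segment's mean", {
  part <- partitionChromosomes(c(`1` = 1000), k = 1)
  gr <- segDf("s1", c(1, 301), c(300, 1000), c(0.9, -0.2))
  expect_equal(unname(featureMatrix(
    cslvFromSegments(gr, part, segPolicy = "longest"))[1, 1]), -0.2)
  # equal overlap: the later record wins
  gr2 <- segDf("s1", c(1, 501), c(500, 1000), c(0.9, -0.2))
  expect_equal(unname(featureMatrix(
    cslvFromSegments(gr2, part, segPolicy = "longest"))[1, 1]), -0.2)
})

test_that("assembly concatenates aligned per-chromosome tables", {
  cfg <- tinyConfig(nCases = 8, nControls = 24, snps = 100)
  truth <- simulateCohort(cfg)
  l2r <- renderL2R(truth)
  part <- partitionChromosomes(cfg@chromSizes, 4)
  tabs <- lapply(l2r, cslvFromL2R, partition = part)
  feats <- assembleFeatures(tabs)
  expect_equal(dim(featureMatrix(feats)), c(32L, 8L))
  # shuffled sample order in one input is realigned by id
  shuffled <- tabs[[2]][, sample(colnames(tabs[[2]]))]
  feats2 <- assembleFeatures(list(tabs[[1]], shuffled))
  expect_equal(featureMatrix(feats2), featureMatrix(feats))
  # single sample stays a single row
  one <- assembleFeatures(lapply(tabs, function(t) t[, 1]))
  expect_equal(nrow(featureMatrix(one)), 1L)
  # sample mismatch errors with the symmetric difference
  expect_error(assembleFeatures(list(tabs[[1]], tabs[[2]][, -3])),
               "missing from table 2")
  # full-scale contracts: 22 tables of 4 columns make 88 features
  p88 <- partitionChromosomes(grch37ChromSizes(), 4)
  small <- lapply(unique(as.character(GenomicRanges::seqnames(p88))),
                  function(ch) {
    sp <- p88[as.character(GenomicRanges::seqnames(p88)) == ch]
    m <- matrix(0, nrow = 2, ncol = 4,
                dimnames = list(c("a", "b"), sp$featureName))
    CSLVFeatureSet(m)
  })
  expect_equal(ncol(featureMatrix(assembleFeatures(small))), 88L)
})
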