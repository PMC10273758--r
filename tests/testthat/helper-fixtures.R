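# Small in-code fixtures shared across test files.

# A compact simulation configuration: two short chromosomes, four segments
# each, used wherever the full autosome set is unnecessary.
tinyConfig <- function(nCases = 30, nControls = 90, seed = 11,
                       snps = 200, tau = 0.1, sigma = 0.2,
                       riskSpec = RiskSpec(c("1_q0" = 10)),
                       prevalence = 0.25, threshold = 0.01,
                       chromSizes = c(`1` = 4e6, `2` = 3e6),
                       segments = 4) {
  SimulationConfig(
    nCases = nCases, nControls = nControls, chromSizes = chromSizes,
    snpsPerChromosome = snps, segmentsPerChromosome = segments,
    personSegmentSd = tau, snpNoiseSd = sigma, riskSpec = riskSpec,
    targetPrevalence = prevalence, segReportThreshold = threshold,
    seed = seed)
}

# A labeled cohort whose risk depends on a couple of features; built through
# the ground-truth offsets directly (no rendering noise) for fast model tests.
toyCohort <- function(n = 200, seed = 42, informative = c("1_q0", "2_q1"),
                      beta = 8, prevalence = 0.3) {
  cfg <- tinyConfig(nCases = ceiling(n * prevalence),
                    nControls = n - ceiling(n * prevalence),
                    seed = seed,
                    riskSpec = RiskSpec(setNames(rep(beta, length(informative)),
                                                 informative)),
                    prevalence = prevalence)
  truth <- simulateCohort(cfg)
  feats <- CSLVFeatureSet(trueOffsets(truth))
  LabeledCohort(feats, labels = unname(cohortLabels(truth)),
                provenance = "synthetic")
}

# A 50-row phenotype fixture exercising every case/control rule branch.
rulePhenotypes <- function() {
  set.seed(99)
  ids <- sprintf("R%02d", 1:50)
  sex <- rep(c("F", "M"), times = c(40, 10))
  df <- data.frame(sample_id = ids, sex = sex,
                   self_report_cancer = FALSE, registry_cancer = FALSE,
                   cancer_type = "", stringsAsFactors = FALSE)
  df[1:10, c("self_report_cancer", "registry_cancer")] <- TRUE  # both flags
  df$cancer_type[1:10] <- "breast"
  df[11:15, "self_report_cancer"] <- TRUE                       # self only
  df$cancer_type[11:15] <- "breast"
  df[16:18, "registry_cancer"] <- TRUE                          # registry only
  df$cancer_type[16:18] <- "breast"
  df[19:22, c("self_report_cancer", "registry_cancer")] <- TRUE # other cancer
  df$cancer_type[19:22] <- "lung"
  # rows 23:40 cancer-free women; rows 41:50 men (one with cancer)
  df[41, c("self_report_cancer", "registry_cancer")] <- TRUE
  df$cancer_type[41] <- "colon"
  df
}

featuresForIds <- function(ids, p = 3, seed = 7) {
  set.seed(seed)
  m <- matrix(rnorm(length(ids) * p), nrow = length(ids),
              dimnames = list(ids, paste0(rep("1", p), "_q", seq_len(p) - 1)))
  CSLVFeatureSet(m)
}
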