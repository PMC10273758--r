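---
title: "Chromosomal-scale length variation: model, simulator and evaluation design"
author: "CSLVRisk authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromosomal-scale length variation: model, simulator and evaluation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CSLVRisk)
```

## The quantity being computed

Germline copy-number state measured on a SNP array is usually summarized
locus by locus. Chromosomal-scale length variation (CSLV) instead summarizes
it over very large spans: the CSLV value of a chromosome segment is the mean
log2 copy-ratio (`l2r`) over that span, interpreted as the person's effective
"length" deviation for that stretch of genome — 0 for a nominal diploid
segment, positive where material is gained, negative where it is lost.
Because chromosomal rearrangements accumulate in the germline and are
constant over the lifespan, a small panel of such numbers (here 4 per
autosome, 88 in all, or one per chromosome for segmented input, 23 with X)
is a compact genome characterization that machine-learning classifiers can
consume directly, and age can never be a confounder of.

Two input representations are supported, mirroring the two public data
shapes the method targets:

* **Per-SNP matrices** (`L2RMatrix`): one row per probe position, one column
  per sample. The CSLV value of a span is the arithmetic mean of all
  non-missing probe values falling inside it (`cslvFromL2R()`).
* **Segmented records** (SEG-like, `readSeg()`): intervals with a segment
  mean equal to log2(copies/2). The CSLV value is the bp-length-weighted
  mean of the segment means overlapping the span (`cslvFromSegments()`),
  with unrecorded base pairs contributing the diploid value 0 — segmentation
  pipelines do not emit records for normal regions, so absence of evidence
  is read as two copies.

Spans come from `partitionChromosomes()`: `k` equal-width bp spans per
chromosome, remainder base pairs assigned to the earliest spans so widths
differ by at most 1 bp. Partitioning is by base pairs rather than by probe
count because bp coordinates are stable across array designs.

### Numerical choices and degenerate inputs

* A span with no observed probes (or fully missing) gets 0, consistent with
  the diploid-gap convention; missing cells are excluded from means, never
  imputed.
* Overlapping same-sample segment records are resolved by later-record
  precedence. Upstream segmentation emits disjoint records, so this is a
  robustness rule only; it is exercised against a per-bp brute-force oracle
  in the tests.
* An alternative `segPolicy = "longest"` reports the single dominant
  overlapping record's mean instead of the weighted mean, since a
  whole-chromosome characterization from segmented data can also be read as
  "the mean of the one big segment". The weighted mean is the default: it
  is conservation-consistent (complete disjoint coverage reduces to the
  length-weighted mean) and continuous in the record boundaries.
* Coordinates are 1-based inclusive end to end (the SEG convention); the
  internal containers are `GRanges`, which use the same convention, so no
  half-open conversion layer exists anywhere.
* Chromosome names are normalized by stripping a `chr` prefix and
  upper-casing X; Y is rejected, as masked germline CNV releases exclude it.

## The synthetic cohort generator

No individual-level biobank or tumor-atlas data can ship with a package, so
all end-to-end evidence comes from a simulator whose statistical structure
matches what the feature definition assumes:

1. **True offsets.** Person `p` carries `delta[p, s] ~ N(0, tau)`
   independently for every segment `s` (`simulateTrueOffsets()`), with
   `tau = personSegmentSd = 0.1` l2r units by default — large chromosomal
   spans deviate from diploid by a few percent of a copy on average.
2. **Labels.** Case probability is `plogis(c + eta)` where `eta` contains
   linear terms `beta_s * delta[p, s]` and pairwise products
   `gamma_st * delta[p, s] * delta[p, t]` (`RiskSpec`). The intercept `c` is
   calibrated by root finding so the cohort mean probability equals the
   target prevalence to within 1e-6, then labels are Bernoulli draws
   (`calibrateAndAssignLabels()`). Default prevalence is 0.25, matching a
   roughly 1:3 case/control design.
3. **Per-SNP rendering.** `snpsPerChromosome` evenly spaced probes report
   their segment's offset plus `N(0, sigma)` noise, `sigma = snpNoiseSd =
   0.2` — per-probe noise dominates the signal, and only averaging over
   hundreds of probes per span recovers it, which is exactly the regime the
   method claims to work in. With `m` probes per span the feature noise is
   `sigma / sqrt(m)`; recovery of the true offsets at correlation above
   0.95 is expected (and tested) whenever `sigma / sqrt(m) < tau / 3`.
4. **Segmented rendering.** One record per (person, segment) whose |offset|
   reaches `segReportThreshold` (default 0.01); smaller offsets produce no
   record, mimicking "normal regions are not recorded". At the default
   threshold about 92% of segments are reported under `tau = 0.1`.
5. **Phenotypes.** `renderPhenotypes()` writes tables consistent with the
   two cohort rule sets, so the cohort builders are exercised end to end.

The default `strongSignalRiskSpec()` spreads eight linear effects
(|beta| = 12) and four interaction effects (|gamma| = 150) across the
genome. With `tau = 0.1` the linear predictor has SD about 3.7, a strong
but noisy signal: the Bayes-optimal scorer sits well above AUC 0.9 while
finite-sample learners on 88 features land in the mid 0.8s — deliberately
in the regime where the stacked ensemble has something to gain and decile
tables are steep but not degenerate.

**What the simulator does not emulate:** linkage structure, GC waves and
batch effects, allele-specific intensities, correlated offsets between
segments (real rearrangements span segment boundaries), population
stratification, and any particular empirical distribution of real CSLV
values — the Gaussian independent-offset model is an explicit assumption.
Passing recovery and AUC tests on this simulator therefore demonstrates the
pipeline's correctness and its statistical machinery, not real-data
performance.

## Cohort rules and splitting

`buildUkbCohort()` takes as cases only women flagged as breast cancer by
*both* self report and a cancer registry, and as controls only women with no
cancer record of any kind; everyone else (men, single-source cases, women
with other cancers) is dropped. `buildTcgaCohort()` reflects a cancer-only
cohort: cases are women with breast cancer, controls women with any other
cancer. Age is never a feature: the feature schema is CSLV columns only,
and the builders refuse an `age` column outright.

Splitting (`makeSplits()`) holds out 15% by default — mirroring an
889-of-5925 evaluation set — and stratifies by label so the test prevalence
matches the cohort to within one sample. Stratification is a design choice
the underlying procedure leaves open; it stabilizes per-repeat AUCs at
these prevalences. All seeds are derived reproducibly from the plan seed,
so an entire repeated evaluation is a pure function of its inputs.

## Classifiers and the stacked ensemble

Five families are provided: gradient boosting (xgboost, 100 rounds, depth 3,
eta 0.1), probability random forests (ranger, 300 trees), a feedforward
network, logistic regression, and a super-learner stacked ensemble. The
network has one hidden layer of 32 logistic units on standardized inputs —
the single-hidden-layer architecture is the package's choice, sized so the
network can express the pairwise interactions the risk model contains.
There is no automatic model search with a time budget: a fixed
configuration per family keeps results reproducible, and the evaluation
surface here is synthetic-data recovery, not leaderboard replication.

The stacked ensemble follows the super-learner recipe strictly: base
learners are refit on each of `foldCount` stratified folds' complements,
their out-of-fold predictions form the meta-feature matrix, and a logistic
meta-learner is fit on those — never on in-fold predictions. The tests
include a deliberately leaky variant (meta-learner fit on in-sample base
predictions) and verify it looks better on training meta-features and no
better held out.

## Evaluation: AUC intervals and the decile table

`aucScore()` is the Mann–Whitney pair-counting estimate with ties credited
0.5, computed from midranks; it is checked against a trapezoidal ROC
integration oracle to 1e-12 and is invariant under monotone transforms of
the scores. `evaluateRepeated()` reports the mean held-out AUC over the
plan's repeats with a one-sample 95% t-interval, after a Shapiro–Wilk
normality check that warns rather than fails.

**A caveat the package states loudly:** the t-interval treats per-repeat
AUCs as independent, but every repeat reuses the same finite cohort, so the
AUCs are strongly correlated and the interval is anti-conservative. On null
cohorts (labels independent of features) the interval covers 0.5 in well
under the nominal 95% of independent cohort draws — in our own measurements
roughly half the time — because it concentrates around the particular
cohort's chance deviation from 0.5. The procedure is implemented as
specified because it is the procedure being reproduced, and the acceptance
suite keeps the null-coverage check as stated even though this correlation
defect can legitimately fail it; a Nadeau–Bengio-style variance correction
would be the remedy if the interval, rather than the point estimate, were
the scientific product.

`decileRiskTable()` ranks an evaluated set by score (stable descending
sort), splits it into ten deciles — with `n = 10q + r` the top decile gets
`q` members and the remainder goes one each to deciles 2 through `r + 1`,
so 889 samples give 88, 89, ..., 89 — and reports each decile's odds ratio
against the *whole* set, `OR = (a_d / b_d) / (A / B)`: enrichment relative
to "the average woman", reference group including the decile itself. The
95% interval is Woolf's log-normal approximation
`exp(log(OR) ± 1.959964 * sqrt(1/a + 1/b + 1/A + 1/B))`, with the
Haldane–Anscombe 0.5 correction (flagged) when a count is zero. Woolf was
chosen because it reproduces the published middle-decile intervals from
their printed counts; the published top-decile interval differs from exact
Woolf in the second significant figure, and the published decile-4 upper
endpoint sits a rounding hair away (exact 1.0506 vs printed 1.0) — both are
documented and neither is chased with alternative rounding.

`importanceSummary()` uses TreeSHAP contributions (via xgboost) for
gradient-boosting models — per-feature mean |SHAP| with the signed
per-sample matrix retained, additivity checked against the model margin —
and seeded permutation importance (mean AUC drop over 10 permutations) for
every other family. On cohorts simulated with the default distributed risk
spec, the largest single-feature share of total importance stays below
0.5: no one segment is responsible for a majority of the predictive value.

## Problem sizes used by the shipped checks

The package's own evaluation runs at deliberately modest sizes chosen to
exercise every code path: the end-to-end cohort has 2,000 persons with 88
features computed from rendered segment records (a scaled version of the
6,000-person design), the recovery check uses two chromosomes at 1,000
SNPs each, and oracle comparisons use toy chromosomes of a few kb where
per-bp brute force is exact. Sample SD bounds, prevalence bounds and
tail-fraction checks are all stated with explicit binomial tolerances at
their stated n.

## Known limitations

* The Gaussian independent-offset generative model is an assumption; real
  CSLV distributions are unknown to this package.
* The repeated-split t-interval is anti-conservative (above).
* Whether quarter boundaries should use chromosome length or observed probe
  extent is unspecified upstream; chromosome length is the default as the
  reproducible choice.
* The segmented path cannot distinguish "diploid" from "not measured";
  both aggregate as 0.
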