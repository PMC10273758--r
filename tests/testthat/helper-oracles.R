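# Independent brute-force oracles. These deliberately share no code with the
# package implementation they check.

# AUC by trapezoidal integration of the empirical ROC curve.
trapezoidAuc <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  tpr <- c(0, vapply(thr, function(t) sum(scores >= t & labels == 1) / n1,
                     numeric(1)))
  fpr <- c(0, vapply(thr, function(t) sum(scores >= t & labels == 0) / n0,
                     numeric(1)))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Per-bp accumulation of segment records over a span: walks every base pair.
perBpSpanMean <- function(records, spanStart, spanEnd, gapValue = 0) {
  bp <- rep(gapValue, spanEnd - spanStart + 1)
  for (i in seq_len(nrow(records))) {  # later records overwrite earlier ones
    lo <- max(records$start[i], spanStart)
    hi <- min(records$end[i], spanEnd)
    if (lo <= hi)
      bp[(lo - spanStart + 1):(hi - spanStart + 1)] <- records$mean[i]
  }
  mean(bp)
}

# Decile of each element by explicit sort-and-slice.
sortSliceDeciles <- function(scores) {
  n <- length(scores)
  q <- n %/% 10
  r <- n %% 10
  sizes <- rep(q, 10)
  if (r > 0) sizes[2:(r + 1)] <- sizes[2:(r + 1)] + 1
  ord <- order(-scores, seq_len(n))
  out <- integer(n)
  pos <- 1
  for (d in 1:10) {
    out[ord[pos:(pos + sizes[d] - 1)]] <- d
    pos <- pos + sizes[d]
  }
  out
}

# Closed-form one-sample t-interval.
closedFormT <- function(x, conf = 0.95) {
  n <- length(x)
  half <- qt(1 - (1 - conf) / 2, n - 1) * sd(x) / sqrt(n)
  c(mean(x) - half, mean(x) + half)
}
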