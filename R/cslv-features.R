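# CSLV feature computation: mean log2-ratio ("length") over chromosome
# segments, from per-SNP matrices or from segmented CNV records.

#' Partition chromosomes into equal-width segments
#'
#' Divides each chromosome into `k` contiguous spans of (near-)equal bp
#' width.  When the length is not divisible by `k`, the remainder base pairs
#' are assigned one each to the earliest spans, so widths differ by at most
#' 1 bp.  With 22 autosomes and `k = 4` this yields the 88 quarter-chromosome
#' features; with chromosomes 1-22 plus X and `k = 1`, the 23 whole-chromosome
#' features.
#'
#' @param sizes named numeric vector of chromosome lengths in bp (see
#'   [readChromSizes()] or [grch37ChromSizes()]).
#' @param k segments per chromosome (>= 1).
#' @param includeX keep the X chromosome if present (`FALSE` drops it; `TRUE`
#'   requires it).
#' @return a `GRanges` of spans with metadata columns `segmentIndex`
#'   (0-based) and `featureName` (`<chrom>_q<index>`); seqlengths carry the
#'   chromosome sizes.
#' @examples
#' partitionChromosomes(c(`1` = 10), k = 4)  # widths 3,3,2,2
#' @export
partitionChromosomes <- function(sizes, k, includeX = FALSE) {
  stopifnot(k >= 1)
  k <- as.integer(k)
  if (is.null(names(sizes)) || any(!nzchar(names(sizes))))
    stop("chromosome sizes must be named")
  chroms <- normalizeChromName(names(sizes))
  names(sizes) <- chroms
  if (includeX) {
    if (!"X" %in% chroms)
      stop("unknown chromosome requested: X not present in sizes")
  } else {
    sizes <- sizes[chroms != "X"]
    chroms <- names(sizes)
  }
  if (any(sizes < k))
    stop("chromosome shorter than the number of segments requested")
  spans <- lapply(chroms, function(ch) {
    L <- as.numeric(sizes[[ch]])
    base <- L %/% k
    r <- L %% k
    widths <- base + as.numeric(seq_len(k) <= r)
    ends <- cumsum(widths)
    starts <- c(1, head(ends, -1L) + 1)
    GRanges(seqnames = ch, ranges = IRanges(start = starts, end = ends),
            segmentIndex = seq_len(k) - 1L,
            featureName = cslvFeatureNames(ch, k))
  })
  gr <- suppressWarnings(do.call(c, spans))
  GenomeInfoDb::seqlengths(gr) <- sizes[GenomeInfoDb::seqlevels(gr)]
  gr
}

#' CSLV features from a per-SNP log2-ratio matrix
#'
#' The CSLV value ("length") of a segment is the arithmetic mean of all
#' non-missing l2r values at SNPs whose position falls inside the segment's
#' span.  A span containing no observed SNPs gets 0, the diploid expectation.
#'
#' @param x an [L2RMatrix-class] for one chromosome.
#' @param partition spans from [partitionChromosomes()]; must include the
#'   matrix's chromosome.
#' @return a [CSLVFeatureSet-class] holding this chromosome's feature
#'   columns for every sample.
#' @seealso [cslvFromSegments()], [assembleFeatures()]
#' @export
cslvFromL2R <- function(x, partition) {
  stopifnot(is(x, "L2RMatrix"))
  spans <- partition[as.character(seqnames(partition)) == x@chromosome]
  if (!length(spans))
    stop("chromosome ", x@chromosome, " not present in the partition")
  spans <- spans[order(start(spans))]
  vals <- x@values
  # spans tile the chromosome, so a position's span is found by its start
  grp <- findInterval(x@positions, start(spans))
  grp <- factor(grp, levels = seq_along(spans))
  obs <- !is.na(vals)
  v0 <- vals
  v0[!obs] <- 0
  sums <- rowsum(v0, grp)          # only spans that contain SNPs
  counts <- rowsum(obs + 0L, grp)
  full <- matrix(0, nrow = length(spans), ncol = ncol(vals))
  cnt <- matrix(0, nrow = length(spans), ncol = ncol(vals))
  idx <- as.integer(rownames(sums))
  full[idx, ] <- sums
  cnt[idx, ] <- counts
  means <- full / cnt
  means[cnt == 0] <- 0             # empty span: diploid expectation
  features <- t(means)
  rownames(features) <- x@sampleIds
  colnames(features) <- spans$featureName
  CSLVFeatureSet(features, rowData = spanRowData(spans))
}

spanRowData <- function(spans) {
  DataFrame(chromosome = as.character(seqnames(spans)),
            segmentIndex = spans$segmentIndex,
            start = start(spans), end = end(spans),
            row.names = spans$featureName)
}

# Later-record-wins resolution of overlapping segments for one sample:
# walking the records in reverse, each record contributes only the parts of
# its interval not claimed by a later record.
.resolveLaterWins <- function(gr) {
  if (length(gr) <= 1L) return(gr)
  covered <- GRanges()
  pieces <- vector("list", length(gr))
  for (i in rev(seq_along(gr))) {
    eff <- GenomicRanges::setdiff(gr[i], covered, ignore.strand = TRUE)
    if (length(eff)) {
      mcols(eff)$segmentMean <- rep(mcols(gr[i])$segmentMean, length(eff))
      pieces[[i]] <- eff
    }
    covered <- GenomicRanges::union(covered, gr[i], ignore.strand = TRUE)
  }
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (!length(pieces)) return(GRanges(segmentMean = numeric(0)))
  suppressWarnings(do.call(c, pieces))
}

#' CSLV features from segmented CNV records
#'
#' Aggregates SEG-style records into per-span CSLV values.  With the default
#' `"weighted"` policy the value is the bp-length-weighted mean of the
#' segment means overlapping the span, with uncovered base pairs contributing
#' `gapValue` (default 0: unrecorded regions are taken as normal diploid).
#' The `"longest"` policy instead reports the segment mean of the single
#' record with the largest overlap, reflecting pipelines that characterize a
#' chromosome by its dominant segment.
#'
#' Overlapping records for the same sample are resolved by later-record
#' precedence (upstream segmentation emits disjoint segments, so this is a
#' robustness rule).  Records extending beyond the chromosome length are
#' clipped with a warning.
#'
#' @param records a `GRanges` with metadata columns `sampleId` and
#'   `segmentMean` (see [readSeg()] or [renderSegmentRecords()]).
#' @param partition spans from [partitionChromosomes()].
#' @param gapValue value assigned to uncovered bp (default 0).
#' @param samples sample ids to report; defaults to those present in
#'   `records`.  Samples with no records get `gapValue` everywhere.
#' @param segPolicy `"weighted"` (default) or `"longest"`.
#' @return a [CSLVFeatureSet-class] covering every chromosome in the
#'   partition.
#' @export
cslvFromSegments <- function(records, partition, gapValue = 0,
                             samples = NULL,
                             segPolicy = c("weighted", "longest")) {
  segPolicy <- match.arg(segPolicy)
  stopifnot(is(records, "GRanges"),
            all(c("sampleId", "segmentMean") %in% colnames(mcols(records))))
  partition <- partition[order(match(as.character(seqnames(partition)),
                                     GenomeInfoDb::seqlevels(partition)),
                               start(partition))]
  bad <- setdiff(unique(as.character(seqnames(records))),
                 GenomeInfoDb::seqlevels(partition))
  if (length(bad))
    stop("records on chromosomes absent from the partition: ",
         paste(bad, collapse = ", "))
  if (is.null(samples)) samples <- unique(records$sampleId)
  lens <- GenomeInfoDb::seqlengths(partition)
  recLens <- lens[as.character(seqnames(records))]
  if (any(end(records) > recLens | start(records) < 1)) {
    warning("clipping segment records extending beyond chromosome bounds")
    start(records) <- pmax(start(records), 1L)
    end(records) <- pmin(end(records), recLens)
  }
  nSpan <- length(partition)
  features <- matrix(as.numeric(gapValue), nrow = length(samples),
                     ncol = nSpan,
                     dimnames = list(samples, partition$featureName))
  sampleIdx <- match(records$sampleId, samples)
  keep <- !is.na(sampleIdx)
  records <- records[keep]
  sampleIdx <- sampleIdx[keep]
  if (!length(records))
    return(CSLVFeatureSet(features, rowData = spanRowData(partition)))

  hits <- GenomicRanges::findOverlaps(records, partition)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  w <- width(GenomicRanges::pintersect(records[q], partition[s]))
  spanW <- width(partition)

  if (segPolicy == "weighted") {
    key <- (sampleIdx[q] - 1) * nSpan + s
    contrib <- rowsum(w * records$segmentMean[q], key)
    covered <- rowsum(w, key)
    kk <- as.numeric(rownames(contrib))
    si <- (kk - 1) %/% nSpan + 1
    sp <- (kk - 1) %% nSpan + 1
    features[cbind(si, sp)] <-
      (contrib[, 1] + (spanW[sp] - covered[, 1]) * gapValue) / spanW[sp]
    # samples whose own records overlap each other need later-record
    # precedence; a sorted sweep per (sample, chromosome) finds them
    o <- order(sampleIdx, as.character(seqnames(records)), start(records))
    si <- sampleIdx[o]
    ch <- as.character(seqnames(records))[o]
    st <- start(records)[o]
    en <- end(records)[o]
    nr <- length(o)
    newGrp <- c(TRUE, si[-1] != si[-nr] | ch[-1] != ch[-nr])
    runningEnd <- stats::ave(en, cumsum(newGrp), FUN = cummax)
    ov <- c(FALSE, st[-1] <= runningEnd[-nr]) & !newGrp
    clashing <- unique(si[ov])
    for (si1 in clashing) {
      eff <- .resolveLaterWins(records[sampleIdx == si1])
      h1 <- GenomicRanges::findOverlaps(eff, partition)
      q1 <- S4Vectors::queryHits(h1)
      s1 <- S4Vectors::subjectHits(h1)
      w1 <- width(GenomicRanges::pintersect(eff[q1], partition[s1]))
      contrib1 <- rowsum(w1 * eff$segmentMean[q1], s1)
      covered1 <- rowsum(w1, s1)
      sp1 <- as.integer(rownames(contrib1))
      features[si1, ] <- gapValue
      features[si1, sp1] <-
        (contrib1[, 1] + (spanW[sp1] - covered1[, 1]) * gapValue) / spanW[sp1]
    }
  } else {
    # largest overlap wins; ties broken in favour of the later record
    key <- (sampleIdx[q] - 1) * nSpan + s
    ord <- order(key, w, q)
    pick <- ord[!duplicated(key[ord], fromLast = TRUE)]
    features[cbind(sampleIdx[q[pick]], s[pick])] <-
      records$segmentMean[q[pick]]
  }
  CSLVFeatureSet(features, rowData = spanRowData(partition))
}

#' Column-concatenate per-chromosome feature tables
#'
#' @param tables list of [CSLVFeatureSet-class] objects over identical sample
#'   sets (any order; output is aligned to the first table's order).
#' @return a single [CSLVFeatureSet-class].
#' @export
assembleFeatures <- function(tables) {
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, is, logical(1), "CSLVFeatureSet")))
  ref <- colnames(tables[[1L]])
  for (i in seq_along(tables)) {
    ids <- colnames(tables[[i]])
    extra <- setdiff(ids, ref)
    miss <- setdiff(ref, ids)
    if (length(extra) || length(miss))
      stop("sample sets differ between feature tables; only in table ", i,
           ": {", paste(extra, collapse = ", "), "}; missing from table ",
           i, ": {", paste(miss, collapse = ", "), "}")
    tables[[i]] <- tables[[i]][, ref]
  }
  out <- do.call(rbind, lapply(tables, methods::as,
                               "SummarizedExperiment"))
  new("CSLVFeatureSet", out)
}
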