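# Readers and writers for every on-disk format the pipeline touches.
# All readers are strict: malformed input fails with the file and line
# named, never a silent coercion.

.detectDelim <- function(line) {
  if (grepl("\t", line)) "\t"
  else if (grepl(",", line)) ","
  else "[ ]+"
}

.parseReal <- function(tokens, path, lineNo) {
  isNA <- tokens == "NA" | tokens == ""
  v <- suppressWarnings(as.numeric(tokens))
  bad <- is.na(v) & !isNA
  if (any(bad))
    stop("format error in ", path, " line ", lineNo,
         ": non-numeric token '", tokens[which(bad)[1]], "'")
  v[isNA] <- NA_real_
  v
}

#' Read a headerless per-chromosome l2r matrix
#'
#' The l2r dialect is a headerless, delimiter-separated (tab, comma or
#' space; auto-detected) matrix with one row per SNP and one column per
#' sample, sample ids in a sidecar one-per-line file, and `NA` or empty
#' tokens marking missing probes.  Row order is position order; if no
#' positions sidecar is given, synthetic 1-based indices are used.
#'
#' @param matrixPath path to the headerless value matrix.
#' @param samplesPath path to the sidecar sample-id list.
#' @param chromosome chromosome name of this file.
#' @param positionsPath optional sidecar of 1-based bp positions, one per row.
#' @return an [L2RMatrix-class].
#' @seealso [writeL2R()]
#' @export
readL2R <- function(matrixPath, samplesPath, chromosome,
                    positionsPath = NULL) {
  ids <- readLines(samplesPath)
  ids <- ids[nzchar(trimws(ids))]
  ids <- trimws(ids)
  if (anyDuplicated(ids))
    stop("format error in ", samplesPath, ": duplicate sample ids")
  lines <- readLines(matrixPath)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("format error in ", matrixPath, ": empty file")
  delim <- .detectDelim(lines[1])
  rows <- strsplit(trimws(lines), delim)
  widths <- lengths(rows)
  if (any(widths != widths[1]))
    stop("format error in ", matrixPath, " line ",
         which(widths != widths[1])[1], ": ragged row (",
         widths[which(widths != widths[1])[1]], " tokens, expected ",
         widths[1], ")")
  if (widths[1] != length(ids))
    stop("format error in ", matrixPath, ": ", widths[1],
         " columns but ", length(ids), " sample ids in ", samplesPath)
  vals <- matrix(NA_real_, nrow = length(rows), ncol = length(ids))
  for (i in seq_along(rows))
    vals[i, ] <- .parseReal(rows[[i]], matrixPath, i)
  if (!is.null(positionsPath)) {
    pos <- .parseReal(trimws(readLines(positionsPath)), positionsPath, NA)
    if (length(pos) != nrow(vals))
      stop("format error in ", positionsPath, ": ", length(pos),
           " positions but ", nrow(vals), " matrix rows")
  } else {
    pos <- seq_len(nrow(vals))
  }
  new("L2RMatrix", chromosome = normalizeChromName(chromosome),
      positions = as.numeric(pos), sampleIds = ids, values = vals)
}

#' Write an l2r matrix in the headerless dialect
#'
#' @param x an [L2RMatrix-class].
#' @param matrixPath,samplesPath,positionsPath output paths; positions are
#'   only written when `positionsPath` is given.
#' @param delim column delimiter (default tab).
#' @return invisibly, `matrixPath`.
#' @export
writeL2R <- function(x, matrixPath, samplesPath, positionsPath = NULL,
                     delim = "\t") {
  stopifnot(is(x, "L2RMatrix"))
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  lines <- apply(x@values, 1, function(r) paste(fmt(r), collapse = delim))
  writeLines(lines, matrixPath)
  writeLines(x@sampleIds, samplesPath)
  if (!is.null(positionsPath))
    writeLines(sprintf("%d", as.integer(x@positions)), positionsPath)
  invisible(matrixPath)
}

.SEG_ALIASES <- list(
  sample = c("sample", "sample_id", "sampleid", "gdc_aliquot", "id"),
  chromosome = c("chromosome", "chrom", "chr"),
  start = c("start", "start_position", "loc.start"),
  end = c("end", "end_position", "loc.end"),
  num_probes = c("num_probes", "numprobes", "probes", "num.mark",
                 "num_mark"),
  segment_mean = c("segment_mean", "seg.mean", "segmean", "segment.mean")
)

#' Read a SEG-like TSV of copy-number segments
#'
#' Expects a header containing (case-insensitively, GDC aliases accepted)
#' Sample, Chromosome, Start, End and Segment_Mean columns, with an optional
#' probe count.  Coordinates are 1-based inclusive; chromosome names are
#' normalized by stripping a "chr" prefix; chromosome Y is rejected (masked
#' germline CNV data exclude it).  The segment mean is log2(copies/2), so 0
#' marks a normal diploid region.
#'
#' @param path path to the TSV.
#' @return a `GRanges` in file order with metadata columns `sampleId`,
#'   `numProbes` (NA when absent) and `segmentMean`.
#' @seealso [writeSeg()], [cslvFromSegments()]
#' @export
readSeg <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1),
                          showProgress = FALSE, data.table = FALSE)
  lower <- tolower(colnames(dt))
  pick <- function(field, required = TRUE) {
    idx <- which(lower %in% .SEG_ALIASES[[field]])
    if (!length(idx)) {
      if (required)
        stop("format error in ", path, ": missing required column '",
             field, "'")
      return(NA_integer_)
    }
    idx[1]
  }
  iSample <- pick("sample"); iChrom <- pick("chromosome")
  iStart <- pick("start"); iEnd <- pick("end")
  iMean <- pick("segment_mean")
  iProbes <- pick("num_probes", required = FALSE)
  if (!nrow(dt)) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(sampleId = character(0),
                           numProbes = integer(0),
                           segmentMean = numeric(0))
    return(gr)
  }
  start <- as.numeric(dt[[iStart]]); end <- as.numeric(dt[[iEnd]])
  if (any(is.na(start)) || any(is.na(end)))
    stop("format error in ", path, " line ",
         which(is.na(start) | is.na(end))[1] + 1L,
         ": non-numeric coordinate")
  bad <- which(end < start)
  if (length(bad))
    stop("record error in ", path, " line ", bad[1] + 1L,
         ": end < start")
  segMean <- as.numeric(dt[[iMean]])
  if (any(!is.finite(segMean)))
    stop("record error in ", path, " line ",
         which(!is.finite(segMean))[1] + 1L,
         ": segment mean must be finite")
  probes <- if (is.na(iProbes)) rep(NA_integer_, nrow(dt))
            else as.integer(dt[[iProbes]])
  GRanges(seqnames = normalizeChromName(dt[[iChrom]]),
          ranges = IRanges(start = start, end = end),
          sampleId = as.character(dt[[iSample]]),
          numProbes = probes,
          segmentMean = segMean)
}

#' Write segments as a SEG-like TSV
#'
#' @param gr a `GRanges` with `sampleId`, `segmentMean` and optionally
#'   `numProbes` metadata columns.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeSeg <- function(gr, path) {
  stopifnot(is(gr, "GRanges"),
            all(c("sampleId", "segmentMean") %in% colnames(mcols(gr))))
  probes <- if ("numProbes" %in% colnames(mcols(gr))) gr$numProbes
            else rep(NA_integer_, length(gr))
  df <- data.frame(
    Sample = gr$sampleId,
    Chromosome = as.character(seqnames(gr)),
    Start = start(gr),
    End = end(gr),
    Num_Probes = probes,
    Segment_Mean = sprintf("%.17g", gr$segmentMean),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a UCSC-style chrom.sizes file
#'
#' Two tab-separated columns (chromosome, length in bp), no header.
#'
#' @param path path to the file.
#' @param dropY silently drop a Y entry instead of failing (default `TRUE`;
#'   public chrom.sizes files list Y even though the pipeline rejects it).
#' @return named numeric vector of chromosome lengths.
#' @export
readChromSizes <- function(path, dropY = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[\t ]+")
  if (any(lengths(parts) < 2))
    stop("format error in ", path, " line ", which(lengths(parts) < 2)[1],
         ": expected two columns")
  nm <- vapply(parts, `[[`, character(1), 1L)
  if (dropY) {
    keep <- !toupper(sub("^chr", "", nm, ignore.case = TRUE)) %in% "Y"
    parts <- parts[keep]; nm <- nm[keep]
  }
  len <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  if (any(is.na(len)))
    stop("format error in ", path, ": non-numeric length for ",
         nm[which(is.na(len))[1]])
  nm <- normalizeChromName(nm)
  if (anyDuplicated(nm))
    stop("format error in ", path, ": duplicate chromosome ",
         nm[anyDuplicated(nm)])
  if (any(len <= 0))
    stop("format error in ", path, ": chromosome length must be > 0")
  stats::setNames(len, nm)
}

#' Write a chrom.sizes file
#' @param sizes named numeric vector of chromosome lengths.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeChromSizes <- function(sizes, path) {
  writeLines(sprintf("%s\t%d", names(sizes), as.integer(sizes)), path)
  invisible(path)
}

.parseFlag <- function(x, path, column) {
  x0 <- tolower(trimws(as.character(x)))
  v <- rep(NA, length(x0))
  v[x0 %in% c("true", "t", "1", "yes")] <- TRUE
  v[x0 %in% c("false", "f", "0", "no")] <- FALSE
  if (any(is.na(v)))
    stop("format error in ", path, " line ", which(is.na(v))[1] + 1L,
         ": cannot parse ", column, " flag '", x[which(is.na(v))[1]], "'")
  v
}

#' Read a phenotype table
#'
#' TSV with header and columns `sample_id`, `sex` ("F"/"M"),
#' `self_report_cancer`, `registry_cancer` (logical flags) and `cancer_type`
#' (label, empty for none).  All rows are retained; case/control rules are
#' applied later by the cohort builders.
#'
#' @param path path to the TSV.
#' @return data.frame with the five columns, flags as logicals.
#' @seealso [buildUkbCohort()], [buildTcgaCohort()]
#' @export
readPhenotypes <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  need <- c("sample_id", "sex", "self_report_cancer", "registry_cancer",
            "cancer_type")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("format error in ", path, ": missing required column(s) ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("format error in ", path, ": duplicate sample id '",
         df$sample_id[anyDuplicated(df$sample_id)], "'")
  data.frame(
    sample_id = df$sample_id,
    sex = toupper(trimws(df$sex)),
    self_report_cancer = .parseFlag(df$self_report_cancer, path,
                                    "self_report_cancer"),
    registry_cancer = .parseFlag(df$registry_cancer, path,
                                 "registry_cancer"),
    cancer_type = ifelse(is.na(df$cancer_type), "",
                         trimws(df$cancer_type)),
    stringsAsFactors = FALSE)
}

#' Write a phenotype table
#' @param phenotypes data.frame as returned by [readPhenotypes()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writePhenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a CSLV feature table
#'
#' TSV with header: a `sample_id` column followed by one column per feature
#' (`<chrom>_q<k>` names), values at 12 significant digits.
#'
#' @param features a [CSLVFeatureSet-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeFeatureTable <- function(features, path) {
  stopifnot(is(features, "CSLVFeatureSet"))
  mat <- featureMatrix(features)
  df <- data.frame(sample_id = rownames(mat), stringsAsFactors = FALSE)
  for (j in colnames(mat)) df[[j]] <- sprintf("%.12g", mat[, j])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a CSLV feature table
#'
#' @param path path written by [writeFeatureTable()].
#' @return a [CSLVFeatureSet-class]; per-feature chromosome and segment
#'   index are reconstructed from the `<chrom>_q<k>` column names.
#' @export
readFeatureTable <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  if (!"sample_id" %in% colnames(df))
    stop("format error in ", path, ": missing required column 'sample_id'")
  if (anyDuplicated(df$sample_id))
    stop("format error in ", path, ": duplicate sample id '",
         df$sample_id[anyDuplicated(df$sample_id)], "'")
  featNames <- setdiff(colnames(df), "sample_id")
  mat <- matrix(NA_real_, nrow = nrow(df), ncol = length(featNames),
                dimnames = list(df$sample_id, featNames))
  for (j in featNames) mat[, j] <- .parseReal(df[[j]], path, NA)
  rd <- NULL
  if (all(grepl("^[^_]+_q[0-9]+$", featNames)) && length(featNames)) {
    rd <- DataFrame(
      chromosome = sub("_q[0-9]+$", "", featNames),
      segmentIndex = as.integer(sub("^.*_q", "", featNames)),
      row.names = featNames)
  }
  CSLVFeatureSet(mat, rowData = rd)
}
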