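# Internal helpers shared across modules.

# Chromosome name normalization: the SEG dialect may prefix "chr" and
# lower-case x; masked germline CNV data exclude Y entirely, so Y is rejected.
normalizeChromName <- function(x) {
  x <- sub("^chr", "", as.character(x), ignore.case = TRUE)
  x[x %in% c("x")] <- "X"
  if (any(toupper(x) == "Y"))
    stop("chromosome Y is not supported (excluded from masked germline CNV data)")
  x
}

# CSLV feature names: <chrom>_q<k> with 0-based segment index.
cslvFeatureNames <- function(chrom, k) {
  paste0(chrom, "_q", seq_len(k) - 1L)
}

# Reproducible child seeds: draw `n` seeds from the parent seed without
# touching the caller's RNG state. Values stay within the 32-bit range.
deriveSeeds <- function(seed, n) {
  old <- globalRNGState()
  on.exit(restoreRNGState(old), add = TRUE)
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

globalRNGState <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restoreRNGState <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Run `expr` under a fixed seed, leaving the caller's RNG untouched.
withSeed <- function(seed, expr) {
  old <- globalRNGState()
  on.exit(restoreRNGState(old), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' GRCh37 chromosome sizes
#'
#' Lengths in bp of chromosomes 1-22 and X on the GRCh37/hg19 assembly, the
#' coordinate system of Affymetrix SNP 6.0 segment calls and of the SNP-array
#' releases this package targets.
#'
#' @param includeX include the X chromosome (default `TRUE`).
#' @return named numeric vector of chromosome lengths.
#' @examples
#' grch37ChromSizes()[c("1", "22", "X")]
#' @export
grch37ChromSizes <- function(includeX = TRUE) {
  sizes <- c(
    `1` = 249250621, `2` = 243199373, `3` = 198022430, `4` = 191154276,
    `5` = 180915260, `6` = 171115067, `7` = 159138663, `8` = 146364022,
    `9` = 141213431, `10` = 135534747, `11` = 135006516, `12` = 133851895,
    `13` = 115169878, `14` = 107349540, `15` = 102531392, `16` = 90354753,
    `17` = 81195210, `18` = 78077248, `19` = 59128983, `20` = 63025520,
    `21` = 48129895, `22` = 51304566, X = 155270560
  )
  if (!includeX) sizes <- sizes[names(sizes) != "X"]
  sizes
}
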