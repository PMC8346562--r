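#' Round half away from zero at a fixed number of decimals
#'
#' Frequencies and percentages in variant-database reports are conventionally
#' printed with half-up rounding (0.00495 -> 0.0050 at 4 decimals), which
#' differs from [base::round()]'s round-half-to-even. This helper is used for
#' every printed-precision value in the package (4-decimal allele frequencies,
#' 1-decimal singleton percentages, 2-decimal all-heterozygous percentages).
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' roundHalfUp(0.39603, 4)   # 0.3960
#' roundHalfUp(499.5)        # 500
#' @export
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Deterministic per-stream seed derived from a master seed and a stream name
# (one stream per chromosome, one for the mitochondrial genome, one for
# sample metadata). Keeps per-chromosome output stable when the chromosome
# set is subset, because each stream depends only on the master seed and the
# stream's own name. Arithmetic in doubles, reduced mod 2^31 - 1 so the
# result is a valid 32-bit seed.
streamSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)) * 131)
  as.integer((as.numeric(seed) * 48271 + h * 2654435 + 11) %% 2147483647)
}

# Sample n distinct integers from 1..len, avoiding `exclude`. Errors when the
# chromosome cannot hold the requested number of sites.
sampleDistinctPositions <- function(len, n, exclude = integer(0), what = "sites") {
  if (n + length(exclude) > len) {
    stop("chromosome overflow: cannot place ", n, " ", what,
         " on a sequence of length ", len,
         " with ", length(exclude), " positions already taken")
  }
  if (n == 0L) return(integer(0))
  pos <- sample.int(len, n)
  bad <- pos %in% exclude | duplicated(pos)
  while (any(bad)) {
    pos[bad] <- sample.int(len, sum(bad))
    bad <- pos %in% exclude | duplicated(pos)
  }
  pos
}

# Is a chromosome name an X chromosome (name ends in X, e.g. "X", "chrX",
# "ECAX")? Used for the autosomes-only convention of singleton reporting:
# the X is called in the same diploid panel but summarized separately.
isXChrom <- function(chrom) grepl("X$", chrom)
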