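#' Per-site ALT-allele count and called-allele number
#'
#' `ac` is the sum of ALT dosages over non-missing genotypes; `an` is
#' ploidy times the number of non-missing genotypes (2N when nothing is
#' missing).
#'
#' @param x an [SnvExperiment-class].
#' @return data.frame with columns `ac` and `an`, one row per site.
#' @export
alleleCounts <- function(x) {
  gt <- dosage(x)
  data.frame(ac = as.integer(rowSums(gt, na.rm = TRUE)),
             an = as.integer(ploidy(x) * rowSums(!is.na(gt))))
}

#' ALT-allele frequency at printed precision
#'
#' @param ac ALT-allele count (0 < ac <= an).
#' @param an total called alleles (> 0).
#' @return ac/an rounded half-up to 4 decimals, the precision at which
#'   population frequencies are tabulated.
#' @examples
#' altFreq(80, 202)  # 0.3960
#' altFreq(1, 202)   # 0.0050
#' @export
altFreq <- function(ac, an) {
  if (any(an == 0)) stop("an must be > 0")
  if (any(ac < 0 | ac > an)) stop("need 0 <= ac <= an")
  roundHalfUp(ac / an, 4)
}

#' Site frequency spectrum
#'
#' Histogram of sites by ALT-allele count k = 1..2N, with the REF-allele
#' orientation (2N - k) alongside to match the conventional plotting axis.
#' The k = 2N bin holds the all-ALT-homozygous (reference-private
#' candidate) sites. Sites with missing genotypes still contribute at
#' their observed ac; monomorphic (ac = 0) sites are excluded.
#'
#' @param x an [SnvExperiment-class].
#' @return data.frame with columns `k`, `n_ref_alleles`, `count`;
#'   attribute `n_sites` gives the total.
#' @export
sfsTable <- function(x) {
  cc <- alleleCounts(x)
  an <- ploidy(x) * ncol(x)
  keep <- cc$ac >= 1L
  tab <- tabulate(cc$ac[keep], nbins = an)
  out <- data.frame(k = seq_len(an), n_ref_alleles = an - seq_len(an),
                    count = tab)
  attr(out, "n_sites") <- sum(keep)
  out
}

#' Identify singletons and attribute each to its carrier sample
#'
#' A singleton (rare variant) is a site whose ALT allele is observed on
#' exactly one of the sampled alleles (ac = 1); its carrier is the unique
#' heterozygous sample. The singleton fraction is reported as a percentage
#' of sites at 1 decimal; by convention the denominator is the autosomal
#' site count (X-chromosome sites are summarized separately), controlled
#' by `autosomesOnly`.
#'
#' @param x an [SnvExperiment-class].
#' @param autosomesOnly restrict both singletons and the denominator to
#'   autosomes (chromosome names not ending in X); default TRUE.
#' @return list of class `RareReport`: `sites` (chrom, pos, carrier),
#'   `per_sample` (named singleton counts, all samples), `n_sites`
#'   (denominator), `fraction_pct` (1-decimal percentage).
#' @export
singletons <- function(x, autosomesOnly = TRUE) {
  if (autosomesOnly) {
    keep <- !isXChrom(as.character(seqnames(x)))
    x <- x[keep, ]
  }
  cc <- alleleCounts(x)
  idx <- which(cc$ac == 1L)
  gt <- dosage(x)
  carrier <- character(length(idx))
  if (length(idx)) {
    sub <- gt[idx, , drop = FALSE] == 1L
    sub[is.na(sub)] <- FALSE
    hit <- which(sub, arr.ind = TRUE)
    if (nrow(hit) != length(idx)) {
      bad <- idx[!idx %in% idx[hit[, 1]]]
      rr <- rowRanges(x)
      stop("singleton site without a heterozygous carrier at ",
           as.character(seqnames(rr))[bad[1]], ":", start(rr)[bad[1]])
    }
    carrier[hit[, 1]] <- colnames(x)[hit[, 2]]
  }
  rr <- rowRanges(x)
  perSample <- setNames(integer(ncol(x)), colnames(x))
  tb <- table(carrier)
  perSample[names(tb)] <- as.integer(tb)
  out <- list(
    sites = data.frame(chrom = as.character(seqnames(rr))[idx],
                       pos = start(rr)[idx], carrier = carrier),
    per_sample = perSample,
    n_sites = nrow(x),
    n_singletons = length(idx),
    fraction_pct = if (nrow(x) > 0)
      roundHalfUp(100 * length(idx) / nrow(x), 1) else NA_real_)
  class(out) <- "RareReport"
  out
}

#' Singleton fraction from site counts
#'
#' @param nSingletons,nSites singleton and total site counts.
#' @return 100 x nSingletons / nSites, half-up rounded to 1 decimal.
#' @examples
#' singletonFraction(802454, 11570312)  # 6.9
#' @export
singletonFraction <- function(nSingletons, nSites) {
  if (nSites <= 0) stop("nSites must be > 0")
  roundHalfUp(100 * nSingletons / nSites, 1)
}

#' @export
print.RareReport <- function(x, ...) {
  cat("RareReport:", x$n_singletons, "singletons among", x$n_sites,
      "sites (", x$fraction_pct, "% )\n")
  invisible(x)
}

#' Mean singleton count per sample group
#'
#' Groups samples by a metadata column (birth year by default) and reports
#' the arithmetic mean of per-sample singleton counts per group, ordered
#' ascending. Used to ask whether earlier-born breeding animals carry fewer
#' rare variants (their variants having spread through the population).
#'
#' @param report a `RareReport` from [singletons()].
#' @param meta sample metadata data.frame with `sample_id` and the group
#'   column; typically [sampleMeta()] of the call set.
#' @param groupKey metadata column to group by (default "birth_year").
#' @return data.frame with columns group, n_samples, mean_singletons.
#' @export
rareByGroup <- function(report, meta, groupKey = "birth_year") {
  counts <- report$per_sample
  if (!all(names(counts) %in% meta$sample_id))
    stop("unknown sample id(s): ",
         paste(setdiff(names(counts), meta$sample_id), collapse = ", "))
  grp <- meta[[groupKey]][match(names(counts), meta$sample_id)]
  agg <- aggregate(list(mean_singletons = as.numeric(counts)),
                   by = list(group = grp), FUN = mean)
  nsam <- aggregate(list(n_samples = rep(1L, length(grp))),
                    by = list(group = grp), FUN = sum)
  out <- merge(agg, nsam, by = "group")
  out <- out[order(out$group), c("group", "n_samples", "mean_singletons")]
  rownames(out) <- NULL
  out
}

#' Reference-private allele candidates
#'
#' Sites where every sampled individual is ALT-homozygous (ac = an, no
#' missing genotypes): the panel is fixed for the ALT allele, so the REF
#' base is most plausibly an allele private to the reference individual.
#'
#' @param x an [SnvExperiment-class].
#' @return data.frame chrom, pos, ac, an, flagged
#'   "reference-private allele candidate".
#' @export
refPrivateSites <- function(x) {
  cc <- alleleCounts(x)
  full <- ploidy(x) * ncol(x)
  idx <- which(cc$ac == cc$an & cc$an == full & cc$ac > 0L)
  rr <- rowRanges(x)
  data.frame(chrom = as.character(seqnames(rr))[idx], pos = start(rr)[idx],
             ac = cc$ac[idx], an = cc$an[idx],
             flag = rep("reference-private allele candidate", length(idx)))
}

#' Look up target positions in a call set
#'
#' Positions are given as "chrom:pos" strings (commas in the position are
#' tolerated). Duplicated targets are deduplicated preserving first
#' occurrence; targets absent from the call set are reported with
#' `found = FALSE` rather than an error, mirroring marker panels whose
#' members may have been excluded during calling.
#'
#' @param x an [SnvExperiment-class].
#' @param targets character vector of "chrom:pos" strings.
#' @return data.frame: target, found, chrom, pos, ref, alt, ac, an, freq,
#'   filter.
#' @export
queryPositions <- function(x, targets) {
  targets <- targets[!duplicated(targets)]
  m <- regmatches(targets, regexec("^([^:]+):([0-9,]+)$", targets))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad))
    stop("malformed position string(s): ", paste(targets[bad], collapse = ", "))
  chrom <- vapply(m, `[[`, character(1), 2)
  pos <- as.integer(gsub(",", "", vapply(m, `[[`, character(1), 3)))
  rr <- rowRanges(x)
  key <- paste0(as.character(seqnames(rr)), ":", start(rr))
  hit <- match(paste0(chrom, ":", pos), key)
  cc <- alleleCounts(x)
  mc <- mcols(rr)
  data.frame(
    target = targets, found = !is.na(hit), chrom = chrom, pos = pos,
    ref = ifelse(is.na(hit), NA, mc$ref[hit]),
    alt = ifelse(is.na(hit), NA, mc$alt[hit]),
    ac = ifelse(is.na(hit), NA, cc$ac[hit]),
    an = ifelse(is.na(hit), NA, cc$an[hit]),
    freq = ifelse(is.na(hit), NA,
                  roundHalfUp(cc$ac[hit] / pmax(cc$an[hit], 1L), 4)),
    filter = ifelse(is.na(hit), "not in call set",
                    ifelse(mc$filter[hit] == "", "PASS", mc$filter[hit])))
}
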