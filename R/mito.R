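#' Build per-sample mitochondrial haplotypes
#'
#' The mitochondrial genome is haploid and maternally inherited, so each
#' sample carries a single haplotype over the variable positions. Diploid-
#' coded mitochondrial records with heterozygous calls indicate a coding
#' or calling problem and are rejected with the offending sample and site
#' named.
#'
#' @param x a haploid [SnvExperiment-class] (mitochondrial call set).
#' @param meta sample metadata with `sample_id` and `founder` columns;
#'   defaults to [sampleMeta()] of `x`.
#' @return object of class `MitoHaplotypes`: list with `alleles`
#'   (samples x sites 0/1 matrix), `founder` (named recorded founder
#'   labels), `positions`.
#' @export
buildHaplotypes <- function(x, meta = sampleMeta(x)) {
  gt <- dosage(x)
  if (ploidy(x) != 1L) {
    het <- which(gt == 1L, arr.ind = TRUE)
    if (nrow(het) > 0) {
      stop("heterozygous mitochondrial genotype for sample ",
           colnames(x)[het[1, 2]], " at ",
           as.character(seqnames(x))[het[1, 1]], ":",
           start(rowRanges(x))[het[1, 1]],
           "; mitochondrial calls must be haploid")
    }
    gt <- gt / 2L  # diploid-coded homozygous calls, collapse to haploid
  }
  alleles <- t(gt)
  storage.mode(alleles) <- "integer"
  founder <- setNames(meta$founder[match(rownames(alleles), meta$sample_id)],
                      rownames(alleles))
  out <- list(alleles = alleles, founder = founder,
              positions = start(rowRanges(x)))
  class(out) <- "MitoHaplotypes"
  out
}

#' @export
print.MitoHaplotypes <- function(x, ...) {
  cat("MitoHaplotypes:", nrow(x$alleles), "samples x", ncol(x$alleles),
      "variable sites;", length(unique(x$founder)), "founder label(s)\n")
  invisible(x)
}

#' Consensus haplotype per founder line
#'
#' Per-site majority allele within each founder-labelled group; ties are
#' broken toward the REF allele and flagged. Robust to a single aberrant
#' sample per group, which is what lets a downstream discrepancy scan
#' identify that sample.
#'
#' @param haplotypes a `MitoHaplotypes` from [buildHaplotypes()].
#' @return list of class `MitoConsensus`: `consensus` (founders x sites
#'   0/1 matrix), `ties` (logical matrix of flagged ties).
#' @export
founderConsensus <- function(haplotypes) {
  founders <- sort(unique(haplotypes$founder))
  ns <- ncol(haplotypes$alleles)
  cons <- matrix(0L, nrow = length(founders), ncol = ns,
                 dimnames = list(founders, NULL))
  ties <- matrix(FALSE, nrow = length(founders), ncol = ns,
                 dimnames = list(founders, NULL))
  for (f in founders) {
    sub <- haplotypes$alleles[haplotypes$founder == f, , drop = FALSE]
    nAlt <- colSums(sub)
    n <- nrow(sub)
    cons[f, ] <- as.integer(nAlt > n / 2)        # ties (nAlt == n/2) -> REF
    ties[f, ] <- nAlt * 2L == n & n > 0L & nAlt > 0L
  }
  out <- list(consensus = cons, ties = ties)
  class(out) <- "MitoConsensus"
  out
}

#' Flag pedigree discrepancies from haplotype-consensus distances
#'
#' Each sample's haplotype is compared (Hamming distance) to the consensus
#' of its recorded founder line. Distance 0 is `consistent`; up to
#' `maxPrivate` differences is `mutation_drift` (private mutations
#' accumulated over the generations since the founder). A
#' `lineage_discrepancy` — the signature of a pedigree-registration error —
#' is called when the distance to the recorded line exceeds `maxPrivate`
#' AND the haplotype is strictly closer to some other founder line's
#' consensus: founder lines differ at many sites, so a genuinely
#' misregistered sample sits near another line, whereas a sample that
#' merely accumulated an unusual number of private mutations remains
#' nearest its own line and is reported as drift. With a single founder
#' line no discrepancy can be called.
#'
#' @param haplotypes a `MitoHaplotypes`.
#' @param consensus a `MitoConsensus` from [founderConsensus()]; default
#'   computed from `haplotypes`.
#' @param maxPrivate maximum differences attributable to private mutations
#'   (default 2).
#' @return data.frame: sample_id, founder, distance, nearest_founder,
#'   nearest_distance, verdict.
#' @export
flagDiscrepancies <- function(haplotypes, consensus = founderConsensus(haplotypes),
                              maxPrivate = 2) {
  founder <- haplotypes$founder
  if (any(is.na(founder)))
    stop("sample(s) without founder label: ",
         paste(names(founder)[is.na(founder)], collapse = ", "))
  cons <- consensus$consensus
  # Hamming distance of every sample to every founder consensus
  distAll <- vapply(rownames(cons), function(f) {
    as.integer(rowSums(haplotypes$alleles !=
                         matrix(cons[f, ], nrow = nrow(haplotypes$alleles),
                                ncol = ncol(cons), byrow = TRUE)))
  }, integer(length(founder)))
  distAll <- matrix(distAll, nrow = length(founder),
                    dimnames = list(names(founder), rownames(cons)))
  own <- distAll[cbind(seq_along(founder), match(founder, rownames(cons)))]
  other <- distAll
  other[cbind(seq_along(founder), match(founder, rownames(cons)))] <- NA
  nearestOther <- if (ncol(distAll) > 1L)
    apply(other, 1, which.min) else rep(NA_integer_, length(founder))
  nearestDist <- if (ncol(distAll) > 1L)
    apply(other, 1, min, na.rm = TRUE) else rep(NA_integer_, length(founder))
  verdict <- ifelse(own == 0L, "consistent",
             ifelse(own > maxPrivate & !is.na(nearestDist) &
                      nearestDist < own, "lineage_discrepancy",
                    "mutation_drift"))
  data.frame(sample_id = names(founder), founder = unname(founder),
             distance = own,
             nearest_founder = ifelse(is.na(nearestOther), NA_character_,
                                      rownames(cons)[nearestOther]),
             nearest_distance = as.integer(nearestDist),
             verdict = verdict, row.names = NULL)
}
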