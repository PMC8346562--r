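#' Classify a substitution into strand-symmetric spectrum classes
#'
#' A substitution and its reverse-complement are the same event, so the 12
#' ordered REF>ALT pairs collapse into six classes, reported with the
#' A- or C- reference representative first (e.g. `A>G/T>C`). The four-way
#' rollup merges the two transition classes into `transition` and the two
#' A:C-type transversions (`A>C/T>G` with `C>A/G>T`) into `A:C`, keeping
#' `A:T` (A<->T) and `G:C` (G<->C) as their own classes.
#'
#' @param ref,alt character vectors of single distinct A/C/G/T bases.
#' @return data.frame with columns `class6` and `class4`, one row per
#'   substitution.
#' @examples
#' classifySubstitution("A", "G")   # class6 "A>G/T>C", class4 "transition"
#' @export
classifySubstitution <- function(ref, alt) {
  if (length(ref) == 0L)
    return(data.frame(class6 = character(0), class4 = character(0)))
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (!all(ok)) stop("ref/alt must be A/C/G/T bases")
  if (any(ref == alt)) stop("ref and alt must differ")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  # canonical representative: the orientation whose REF is A or C
  flip <- ref %in% c("G", "T")
  cref <- ifelse(flip, comp[ref], ref)
  calt <- ifelse(flip, comp[alt], alt)
  class6 <- paste0(cref, ">", calt, "/", comp[cref], ">", comp[calt])
  class4 <- ifelse(class6 %in% c("A>G/T>C", "C>T/G>A"), "transition",
            ifelse(class6 == "A>T/T>A", "A:T",
            ifelse(class6 == "C>G/G>C", "G:C", "A:C")))
  data.frame(class6 = class6, class4 = class4)
}

#' Per-chromosome substitution spectrum
#'
#' Counts classified substitutions per chromosome in both the six-class and
#' the four-class resolution. With a 2:1 transition:transversion weight
#' (the mammalian genome-wide norm this package simulates), the transition
#' class is modal.
#'
#' @param x an [SnvExperiment-class].
#' @return data.frame with columns chrom, class6, class4, n (all
#'   chromosome x class6 combinations, including zero counts).
#' @export
substitutionSpectrum <- function(x) {
  cls <- classifySubstitution(mcols(rowRanges(x))$ref,
                              mcols(rowRanges(x))$alt)
  six <- sort(unique(classifySubstitution(
    rep(c("A", "A", "A", "C", "C", "C"), 1),
    c("C", "G", "T", "A", "G", "T"))$class6))
  chrom <- factor(as.character(seqnames(x)), levels = seqlevels(x))
  tab <- table(chrom = chrom, class6 = factor(cls$class6, levels = six))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out)[3] <- "n"
  map <- unique(classifySubstitution(c("A", "A", "A", "C", "C", "C"),
                                     c("C", "G", "T", "A", "G", "T")))
  out$class4 <- map$class4[match(out$class6, map$class6)]
  out[, c("chrom", "class6", "class4", "n")]
}

#' Four-class rollup of a substitution spectrum
#'
#' @param spec output of [substitutionSpectrum()].
#' @return data.frame chrom x class4 with summed counts.
#' @export
spectrumRollup <- function(spec) {
  agg <- aggregate(n ~ chrom + class4, data = spec, FUN = sum)
  agg[order(agg$chrom, agg$class4), ]
}

#' Mean genomic spacing between SNVs
#'
#' "One SNV every k bp": total sequence length divided by the number of
#' SNVs, rounded half-up to the nearest integer.
#'
#' @param totalLengthBp total length of the sequence surveyed (bp).
#' @param nSnvs number of SNVs (> 0).
#' @return integer bp per SNV.
#' @examples
#' meanSpacing(2.41e9, 12173068)  # 198
#' @export
meanSpacing <- function(totalLengthBp, nSnvs) {
  if (nSnvs <= 0) stop("nSnvs must be > 0")
  as.integer(roundHalfUp(totalLengthBp / nSnvs))
}

#' SNV density per chromosome and functional class
#'
#' Density is the site count scaled per chromosome kilobase: count x 1000 /
#' chromosome length. The whole-chromosome denominator matches how such
#' densities are tabulated for variant databases; an alternative per-
#' feature-bp density (count x 1000 / total bp annotated to the class on
#' that chromosome) is exposed as an optional column.
#'
#' @param x an [SnvExperiment-class]; functional classes are taken from the
#'   `ann_class` row metadata, or computed from `annotation` when absent.
#' @param annotation annotation `GRanges` (required when `ann_class` is
#'   absent or `perFeature = TRUE`).
#' @param chromLengths named chromosome lengths; default from `seqlengths(x)`.
#' @param perFeature also compute the per-feature-bp density column.
#' @return data.frame with chrom, class, n, chrom_length_bp,
#'   density_per_kb (and feature_bp, density_per_feature_kb when requested).
#' @export
densityTable <- function(x, annotation = NULL, chromLengths = NULL,
                         perFeature = FALSE) {
  if (is.null(chromLengths)) {
    chromLengths <- seqlengths(x)
    if (any(is.na(chromLengths))) stop("missing chromosome length")
  }
  cls <- mcols(rowRanges(x))$ann_class
  if (is.null(cls) || all(is.na(cls))) {
    if (is.null(annotation)) stop("no ann_class and no annotation supplied")
    cls <- as.character(assignFunctionalClass(x, annotation))
  }
  lv <- c("exon", "utr5", "utr3", "intron", "upstream", "downstream",
          "intergenic")
  chrom <- factor(as.character(seqnames(x)), levels = names(chromLengths))
  tab <- as.data.frame(table(chrom = chrom,
                             class = factor(cls, levels = lv)),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "n"
  if (any(is.na(chromLengths[tab$chrom]))) stop("missing chromosome length")
  tab$chrom_length_bp <- as.numeric(chromLengths[tab$chrom])
  tab$density_per_kb <- tab$n * 1000 / tab$chrom_length_bp
  if (perFeature) {
    if (is.null(annotation)) stop("perFeature density needs the annotation")
    red <- as.data.frame(GenomicRanges::reduce(
      S4Vectors::split(annotation, mcols(annotation)$class)))
    span <- aggregate(width ~ group_name + seqnames, data = red, FUN = sum)
    key <- paste(tab$chrom, tab$class)
    tab$feature_bp <- span$width[match(key, paste(span$seqnames,
                                                  span$group_name))]
    tab$feature_bp[is.na(tab$feature_bp)] <- 0
    tab$density_per_feature_kb <- ifelse(tab$feature_bp > 0,
                                         tab$n * 1000 / tab$feature_bp, NA)
  }
  tab
}

#' Coding-impact summary per chromosome
#'
#' Tabulates synonymous vs non-synonymous (and the start/stop gain/loss
#' classes) among coding sites; sites without an impact annotation
#' (non-coding) are excluded.
#'
#' @param x an [SnvExperiment-class] with `ann_impact` set for coding sites.
#' @return data.frame chrom x impact with counts.
#' @export
impactSummary <- function(x) {
  imp <- mcols(rowRanges(x))$ann_impact
  keep <- !is.na(imp)
  lv <- c("synonymous", "non_synonymous", "start_gained", "start_lost",
          "stop_gained", "stop_lost", "other")
  tab <- as.data.frame(table(
    chrom = factor(as.character(seqnames(x))[keep], levels = seqlevels(x)),
    impact = factor(imp[keep], levels = lv)), stringsAsFactors = FALSE)
  names(tab)[3] <- "n"
  tab
}
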