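#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end findOverlaps
#' @importFrom GenomeInfoDb seqlengths seqlevels seqinfo Seqinfo
#' @importFrom SummarizedExperiment SummarizedExperiment rowRanges rowRanges<- colData assay assays
#' @importFrom stats median rpois rbinom runif setNames aggregate
#' @importFrom utils write.table read.delim
NULL

#' SnvExperiment: a multi-sample biallelic SNV call set
#'
#' The central container of the package, extending
#' [SummarizedExperiment::RangedSummarizedExperiment]. Rows are biallelic
#' SNV sites, columns are samples. The `"gt"` assay holds the ALT-allele
#' dosage per genotype (0/1/2 for diploid calls, 0/1 for haploid
#' mitochondrial calls, `NA` for missing); the optional `"depth"` assay
#' holds per-sample per-site read depth (FORMAT DP).
#'
#' Row metadata columns:
#' \describe{
#'   \item{ref, alt}{single REF/ALT nucleotides (A/C/G/T, distinct).}
#'   \item{qual}{phred-scaled site quality (VCF QUAL column).}
#'   \item{info_dp, info_qd, info_mq0, info_sb}{site-level INFO metrics used
#'     by the hard filters; `NA` when absent from the VCF.}
#'   \item{filter}{semicolon-joined failed-criterion labels, `""` for PASS.}
#'   \item{ann_class}{functional-region class (exon, utr5, utr3, intron,
#'     upstream, downstream, intergenic), optional.}
#'   \item{ann_impact}{coding impact (synonymous, non_synonymous,
#'     start_gained, start_lost, stop_gained, stop_lost, other), optional.}
#' }
#'
#' `metadata(x)$ploidy` is 2 for nuclear call sets and 1 for mitochondrial
#' ones. Column data carries the sample metadata (sample_id, sex,
#' birth_year, founder).
#'
#' @aliases SnvExperiment
#' @export
setClass("SnvExperiment", contains = "RangedSummarizedExperiment")

setValidity("SnvExperiment", function(object) {
  msg <- character(0)
  if (!"gt" %in% names(assays(object)))
    msg <- c(msg, "assay 'gt' (ALT-allele dosage) is required")
  rr <- rowRanges(object)
  mc <- mcols(rr)
  for (col in c("ref", "alt", "qual", "filter"))
    if (!col %in% names(mc)) msg <- c(msg, paste0("rowRanges needs mcol '", col, "'"))
  if (length(msg) == 0 && length(rr) > 0) {
    if (!all(mc$ref %in% c("A", "C", "G", "T")) ||
        !all(mc$alt %in% c("A", "C", "G", "T")))
      msg <- c(msg, "ref/alt must be single A/C/G/T bases")
    else if (any(mc$ref == mc$alt))
      msg <- c(msg, "ref and alt must differ at every site")
    if (any(GenomicRanges::width(rr) != 1L))
      msg <- c(msg, "all sites must have width 1")
    pl <- ploidy(object)
    g <- assay(object, "gt")
    if (!all(is.na(g) | (g >= 0L & g <= pl)))
      msg <- c(msg, paste0("gt dosages must be in 0..", pl, " or NA"))
  }
  if (length(msg)) msg else TRUE
})

#' Construct an SnvExperiment
#'
#' @param chrom,pos chromosome names and 1-based positions, one per site.
#' @param ref,alt REF and ALT bases.
#' @param gt sites x samples integer matrix of ALT dosages (NA = missing).
#' @param depth optional sites x samples read-depth matrix.
#' @param sampleData data.frame of per-sample metadata; must contain
#'   `sample_id` (used as column names).
#' @param chromLengths optional named vector of chromosome lengths.
#' @param qual site quality values (default NA).
#' @param info optional data.frame/list with columns dp, qd, mq0, sb.
#' @param filter failed-filter labels (semicolon-joined; "" = PASS).
#' @param annClass,annImpact optional functional class / coding impact labels.
#' @param ploidy 2 (nuclear, default) or 1 (mitochondrial).
#' @return an [SnvExperiment-class] object with sites sorted by
#'   (chromosome, position).
#' @export
SnvExperiment <- function(chrom, pos, ref, alt, gt, depth = NULL,
                          sampleData = NULL, chromLengths = NULL,
                          qual = NA_real_, info = NULL, filter = "",
                          annClass = NULL, annImpact = NULL, ploidy = 2L) {
  n <- length(pos)
  if (is.matrix(gt)) storage.mode(gt) <- "integer"
  else gt <- matrix(as.integer(gt), nrow = n)
  if (is.null(sampleData)) {
    sampleData <- data.frame(sample_id = paste0("S", seq_len(ncol(gt))))
  }
  stopifnot(nrow(sampleData) == ncol(gt))
  if (is.null(chromLengths)) {
    si <- Seqinfo(seqnames = unique(as.character(chrom)))
  } else {
    si <- Seqinfo(seqnames = names(chromLengths),
                  seqlengths = as.integer(chromLengths))
  }
  gr <- GRanges(chrom, IRanges(pos, width = 1L), seqinfo = si)
  mcols(gr) <- DataFrame(
    ref = as.character(ref), alt = as.character(alt),
    qual = rep_len(as.numeric(qual), n),
    info_dp = numNA(info, "dp", n), info_qd = numNA(info, "qd", n),
    info_mq0 = numNA(info, "mq0", n), info_sb = numNA(info, "sb", n),
    filter = rep_len(as.character(filter), n),
    ann_class = if (is.null(annClass)) rep(NA_character_, n) else as.character(annClass),
    ann_impact = if (is.null(annImpact)) rep(NA_character_, n) else as.character(annImpact)
  )
  assayList <- list(gt = gt)
  if (!is.null(depth)) {
    if (is.matrix(depth)) storage.mode(depth) <- "integer"
    else depth <- matrix(as.integer(depth), nrow = n)
    assayList$depth <- depth
  }
  cd <- DataFrame(sampleData)
  rownames(cd) <- sampleData$sample_id
  assayList <- lapply(assayList, function(m) {
    dimnames(m) <- list(NULL, sampleData$sample_id); m
  })
  se <- SummarizedExperiment(assays = assayList, rowRanges = gr, colData = cd)
  se <- se[order(match(as.character(seqnames(se)), seqlevels(se)), start(se)), ]
  out <- new("SnvExperiment", se)
  metadata(out)$ploidy <- as.integer(ploidy)
  validObject(out)
  out
}

numNA <- function(info, key, n) {
  if (is.null(info) || is.null(info[[key]])) rep(NA_real_, n)
  else rep_len(as.numeric(info[[key]]), n)
}

#' @describeIn SnvExperiment-class ALT-dosage matrix (sites x samples).
#' @param x an SnvExperiment.
#' @export
dosage <- function(x) assay(x, "gt")

#' @describeIn SnvExperiment-class per-sample read-depth matrix, or NULL.
#' @export
readDepth <- function(x) if ("depth" %in% names(assays(x))) assay(x, "depth") else NULL

#' @describeIn SnvExperiment-class ploidy of the call set (2 nuclear, 1 mito).
#' @export
ploidy <- function(x) {
  p <- metadata(x)$ploidy
  if (is.null(p)) 2L else p
}

#' @describeIn SnvExperiment-class failed-filter labels ("" = PASS).
#' @export
filterLabels <- function(x) mcols(rowRanges(x))$filter

#' @describeIn SnvExperiment-class set failed-filter labels.
#' @param value character vector of semicolon-joined labels.
#' @export
`filterLabels<-` <- function(x, value) {
  mcols(rowRanges(x))$filter <- as.character(value)
  x
}

#' @describeIn SnvExperiment-class sample metadata as a data.frame.
#' @export
sampleMeta <- function(x) as.data.frame(colData(x))

#' @describeIn SnvExperiment-class site table (chrom, pos, ref, alt, qual,
#'   INFO metrics, filter, annotation) as a data.frame.
#' @export
siteTable <- function(x) {
  rr <- rowRanges(x)
  data.frame(chrom = as.character(seqnames(rr)), pos = start(rr),
             as.data.frame(mcols(rr)), row.names = NULL)
}

setMethod("show", "SnvExperiment", function(object) {
  pl <- ploidy(object)
  cat("SnvExperiment (", if (pl == 2L) "diploid" else "haploid", "): ",
      nrow(object), " sites x ", ncol(object), " samples\n", sep = "")
  cat("  chromosomes:", paste(seqlevels(object), collapse = ", "), "\n")
  fl <- filterLabels(object)
  cat("  PASS sites:", sum(fl == ""), "of", length(fl), "\n")
  if ("depth" %in% names(assays(object)))
    cat("  mean depth:", round(mean(assay(object, "depth"), na.rm = TRUE), 2), "\n")
})
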