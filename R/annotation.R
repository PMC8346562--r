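#' Deterministically tile gene models to build a functional annotation
#'
#' Lays non-overlapping plus-strand gene models along each chromosome and
#' emits the functional-region intervals used for SNV density analysis:
#' exon, intron, 5'-UTR, 3'-UTR, 5 kb upstream and downstream flanks, and
#' the residual intergenic space. The gene model is fixed (5'-UTR 200 bp,
#' three 1 kb exons separated by two 2 kb introns, 3'-UTR 300 bp; 7.5 kb
#' total), so the annotation is a pure function of the chromosome lengths —
#' no randomness.
#'
#' @param chromLengths named vector of chromosome lengths (bp).
#' @param geneSpacing distance between successive gene starts (default
#'   1e5 bp, leaving most of the chromosome intergenic).
#' @param firstGeneStart start of the first gene on each chromosome.
#' @param flankBp upstream/downstream flank width (default 5000).
#' @param geneStarts optional named list of explicit gene start positions
#'   per chromosome, overriding the regular tiling.
#' @return a `GRanges` with metadata column `class` in \{exon, utr5, utr3,
#'   intron, upstream, downstream, intergenic\}; after precedence
#'   resolution the classes partition every chromosome.
#' @seealso [assignFunctionalClass()], [writeAnnotationBed()]
#' @export
generateAnnotation <- function(chromLengths, geneSpacing = 1e5,
                               firstGeneStart = 50001, flankBp = 5000,
                               geneStarts = NULL) {
  model <- data.frame(
    class = c("utr5", "exon", "intron", "exon", "intron", "exon", "utr3"),
    width = c(200, 1000, 2000, 1000, 2000, 1000, 300))
  geneLen <- sum(model$width)
  pieces <- list()
  for (ch in names(chromLengths)) {
    len <- chromLengths[[ch]]
    starts <- if (!is.null(geneStarts)) geneStarts[[ch]] else
      seq(firstGeneStart, by = geneSpacing,
          length.out = max(0, floor((len - geneLen - firstGeneStart + 1) /
                                      geneSpacing) + 1))
    starts <- starts[starts >= 1 & starts + geneLen - 1 <= len]
    for (gs in starts) {
      off <- cumsum(c(0, model$width[-nrow(model)]))
      featStart <- gs + off
      featEnd <- featStart + model$width - 1
      pieces[[length(pieces) + 1L]] <- data.frame(
        chrom = ch,
        start = c(max(1, gs - flankBp), featStart,
                  min(len, gs + geneLen)),
        end = c(gs - 1, featEnd,
                min(len, gs + geneLen + flankBp - 1)),
        class = c("upstream", model$class, "downstream"))
    }
  }
  ann <- if (length(pieces)) do.call(rbind, pieces) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               class = character(0))
  ann <- ann[ann$start <= ann$end, , drop = FALSE]
  si <- Seqinfo(seqnames = names(chromLengths),
                seqlengths = as.integer(chromLengths))
  gr <- GRanges(ann$chrom, IRanges(ann$start, ann$end), seqinfo = si)
  mcols(gr)$class <- ann$class
  # residual space is intergenic
  gaps <- GenomicRanges::gaps(gr)
  gaps <- gaps[BiocGenerics::strand(gaps) == "*"]
  if (length(gaps)) {
    mcols(gaps)$class <- "intergenic"
    gr <- c(gr, gaps)
  }
  GenomicRanges::sort(gr)
}

#' Assign each site a single functional class by precedence
#'
#' A site overlapped by several annotation intervals gets the highest-
#' precedence class: exon > 5'-UTR > 3'-UTR > intron > upstream >
#' downstream > intergenic. Sites in no interval are intergenic.
#'
#' @param sites an [SnvExperiment-class] or a `GRanges` of site positions.
#' @param annotation annotation `GRanges` with a `class` metadata column.
#' @return factor of classes, one per site, levels in precedence order
#'   (plus intergenic).
#' @export
assignFunctionalClass <- function(sites, annotation) {
  gr <- if (is(sites, "SnvExperiment")) rowRanges(sites) else sites
  sl <- seqlengths(gr)
  known <- !is.na(sl[as.character(seqnames(gr))])
  if (any(known & start(gr) > sl[as.character(seqnames(gr))]))
    stop("site position beyond chromosome length")
  prec <- c("exon", "utr5", "utr3", "intron", "upstream", "downstream",
            "intergenic")
  cls <- rep("intergenic", length(gr))
  hits <- findOverlaps(gr, annotation, ignore.strand = TRUE)
  if (length(hits)) {
    hc <- mcols(annotation)$class[S4Vectors::subjectHits(hits)]
    rank <- match(hc, prec)
    best <- tapply(rank, S4Vectors::queryHits(hits), min)
    cls[as.integer(names(best))] <- prec[best]
  }
  factor(cls, levels = prec)
}

#' Write / read a functional annotation as BED
#'
#' BED uses 0-based half-open coordinates; conversion happens here at the
#' boundary (everything in memory is 1-based inclusive). The class label is
#' stored in the BED name column.
#'
#' @param annotation annotation `GRanges` with `class` metadata column.
#' @param path file path.
#' @return `writeAnnotationBed` returns the path invisibly;
#'   `readAnnotationBed` returns an annotation `GRanges`.
#' @export
writeAnnotationBed <- function(annotation, path) {
  gr <- annotation
  mcols(gr)$name <- mcols(gr)$class
  mcols(gr)$class <- NULL
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' @rdname writeAnnotationBed
#' @param chromLengths optional named lengths to attach as seqinfo.
#' @export
readAnnotationBed <- function(path, chromLengths = NULL) {
  gr <- rtracklayer::import.bed(path)
  mcols(gr) <- DataFrame(class = mcols(gr)$name)
  if (!is.null(chromLengths)) {
    si <- Seqinfo(seqnames = names(chromLengths),
                  seqlengths = as.integer(chromLengths))
    GenomeInfoDb::seqlevels(gr) <- names(chromLengths)
    GenomeInfoDb::seqinfo(gr) <- si
  }
  gr
}
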