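#' Read a multi-sample VCF into an SnvExperiment
#'
#' Parsing is delegated to [VariantAnnotation::readVcf()]; records are then
#' reduced to the biallelic-SNV data model: multi-allelic records and
#' indels are skipped (their count is reported via a message and the
#' `n_skipped` attribute), GT strings become ALT dosages (missing genotype
#' -> `NA`), FORMAT DP becomes the depth assay when present, and the INFO
#' metrics used by the hard filters (DP, QD, MQ0, SB) are carried along
#' (`NA` when absent). Sites are sorted by (chromosome, position) in the
#' header's contig order.
#'
#' @param path path to a VCFv4.2 file.
#' @param ploidy 2 (default) or 1 for haploid mitochondrial VCFs.
#' @return an [SnvExperiment-class]; attribute `n_skipped` counts skipped
#'   records.
#' @export
readSnvVcf <- function(path, ploidy = 2L) {
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path, genome = "unknown")),
    error = function(e) stop("VCF parse error in '", path, "': ",
                             conditionMessage(e)))
  ref <- as.character(VariantAnnotation::ref(vcf))
  altList <- VariantAnnotation::alt(vcf)
  nAlt <- S4Vectors::elementNROWS(altList)
  alt1 <- rep(NA_character_, length(ref))
  alt1[nAlt == 1L] <- as.character(unlist(altList[nAlt == 1L]))
  keep <- nAlt == 1L & nchar(ref) == 1L & !is.na(alt1) & nchar(alt1) == 1L &
    ref %in% c("A", "C", "G", "T") & alt1 %in% c("A", "C", "G", "T") &
    ref != alt1
  nSkipped <- sum(!keep)
  if (nSkipped > 0)
    message("readSnvVcf: skipped ", nSkipped,
            " non-biallelic-SNV record(s)")
  vcf <- vcf[keep, ]
  rr <- SummarizedExperiment::rowRanges(vcf)

  gtChar <- VariantAnnotation::geno(vcf)$GT
  # fast lookup for the common genotype codes; rare forms fall back to a
  # token-level parse
  gtMap <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
             "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L,
             "0" = 0L, "1" = 1L)
  dos <- matrix(unname(gtMap[gtChar]), nrow = nrow(gtChar),
                ncol = ncol(gtChar))
  odd <- is.na(dos) & !gtChar %in% c("./.", ".|.", ".", NA)
  if (any(odd)) {
    dos[odd] <- vapply(strsplit(gsub("|", "/", gtChar[odd], fixed = TRUE), "/"),
                       function(a) if (any(a == ".")) NA_integer_
                       else sum(a == "1"), integer(1))
  }

  depth <- if ("DP" %in% names(VariantAnnotation::geno(vcf)))
    VariantAnnotation::geno(vcf)$DP else NULL

  info <- VariantAnnotation::info(vcf)
  getInfo <- function(key) {
    if (key %in% names(info)) as.numeric(info[[key]])
    else rep(NA_real_, nrow(vcf))
  }
  filt <- VariantAnnotation::fixed(vcf)$FILTER
  filt[is.na(filt) | filt %in% c("PASS", ".")] <- ""

  sl <- seqlengths(vcf)
  chromLengths <- if (all(!is.na(sl))) sl else NULL
  samples <- colnames(gtChar)
  out <- SnvExperiment(
    chrom = as.character(seqnames(rr)), pos = start(rr),
    ref = ref[keep], alt = alt1[keep],
    gt = dos, depth = depth,
    sampleData = data.frame(sample_id = samples),
    chromLengths = chromLengths,
    qual = VariantAnnotation::fixed(vcf)$QUAL,
    info = list(dp = getInfo("DP"), qd = getInfo("QD"),
                mq0 = getInfo("MQ0"), sb = getInfo("SB")),
    filter = filt, ploidy = ploidy)
  attr(out, "n_skipped") <- nSkipped
  out
}

fmtNum <- function(x, digits = 2) {
  ifelse(is.na(x), NA_character_,
         sub("\\.?0+$", "", sprintf(paste0("%.", digits, "f"), x)))
}

#' Write an SnvExperiment as a VCFv4.2 file
#'
#' Emits contig header lines from the chromosome lengths, the INFO keys
#' DP/QD/MQ0/SB plus computed AC/AN, FORMAT GT:DP, and a FILTER column with
#' "PASS" or the semicolon-joined failed-criterion labels. Output is sorted
#' by (chromosome, position) and byte-deterministic, so fixed-seed
#' simulations round-trip identically.
#'
#' @param x an [SnvExperiment-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeSnvVcf <- function(x, path) {
  rr <- rowRanges(x)
  mc <- mcols(rr)
  gt <- dosage(x)
  dp <- readDepth(x)
  pl <- ploidy(x)
  acan <- alleleCounts(x)

  filterDefs <- c(
    lowDP = "Site depth DP < 10", lowQUAL = "Site quality QUAL < 50",
    lowQD = "Quality by depth QD < 1.5",
    highSB = "Strand bias SB > -0.1",
    highMQ0 = "MQ0 >= 4 and MQ0/DP > 0.1",
    snpCluster = "Member of an SNV cluster")
  usedLabels <- unique(unlist(strsplit(mc$filter[mc$filter != ""], ";")))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", seqlevels(x),
            seqlengths(x)[seqlevels(x)]),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Combined site depth\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=MQ0,Number=1,Type=Integer,Description=\"Reads with mapping quality zero\">",
    "##INFO=<ID=SB,Number=1,Type=Float,Description=\"Strand bias\">",
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"ALT allele count in called genotypes\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Total called alleles\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    sprintf("##FILTER=<ID=%s,Description=\"%s\">", usedLabels,
            ifelse(is.na(filterDefs[usedLabels]), "Failed criterion",
                   filterDefs[usedLabels])),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(x)), collapse = "\t"))

  infoField <- function(key, vals, digits = 2, int = FALSE) {
    v <- if (int) ifelse(is.na(vals), NA, format(as.integer(vals),
                                                 scientific = FALSE, trim = TRUE))
    else fmtNum(vals, digits)
    ifelse(is.na(vals), NA_character_, paste0(key, "=", v))
  }
  infoParts <- cbind(
    infoField("DP", mc$info_dp, int = TRUE),
    infoField("QD", mc$info_qd),
    infoField("MQ0", mc$info_mq0, int = TRUE),
    infoField("SB", mc$info_sb),
    paste0("AC=", acan$ac), paste0("AN=", acan$an))
  infoStr <- apply(infoParts, 1, function(p) paste(p[!is.na(p)], collapse = ";"))
  infoStr[infoStr == ""] <- "."

  gtStr <- matrix("./.", nrow = nrow(x), ncol = ncol(x))
  if (pl == 2L) {
    codes <- c("0/0", "0/1", "1/1")
    gtStr[!is.na(gt)] <- codes[gt[!is.na(gt)] + 1L]
  } else {
    gtStr[!is.na(gt)] <- as.character(gt[!is.na(gt)])
    gtStr[is.na(gt)] <- "."
  }
  if (!is.null(dp)) {
    gtStr[] <- paste0(gtStr, ":", ifelse(is.na(dp), ".", dp))
    fmt <- "GT:DP"
  } else fmt <- "GT"

  body <- if (nrow(x) == 0L) character(0) else paste(
    as.character(seqnames(rr)), start(rr), ".", mc$ref, mc$alt,
    ifelse(is.na(mc$qual), ".", fmtNum(mc$qual)),
    ifelse(mc$filter == "", "PASS", mc$filter),
    infoStr, fmt,
    do.call(paste, c(asplit(gtStr, 2), list(sep = "\t"))),
    sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read / write the sample metadata table
#'
#' Tab-separated with columns sample_id, sex, birth_year, founder.
#' @param meta data.frame of sample metadata.
#' @param path file path.
#' @export
writeSampleMeta <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSampleMeta
#' @export
readSampleMeta <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
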