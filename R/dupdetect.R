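#' Candidate collapsed-duplication sites: MAF = 0.5 and all-heterozygous
#'
#' When two near-identical genomic copies are collapsed onto one reference
#' locus, the paralogous difference is called as a pseudo-SNV where every
#' individual appears heterozygous, giving exactly equal REF and ALT counts
#' (MAF = 0.5) and roughly doubled read depth. This operation separates the
#' two conditions: `maf05` means ac = an/2 exactly with no genotype missing
#' (a site whose allele number cannot split evenly is skipped); `allhet`
#' additionally requires every genotype dosage to be 1.
#'
#' @param x a diploid [SnvExperiment-class].
#' @return list: `candidates` (data.frame chrom, pos, allhet for the
#'   MAF = 0.5 sites) and `summary` (n_maf05, n_allhet, percent_allhet at
#'   2 decimals).
#' @export
maf05AllHetSites <- function(x) {
  cc <- alleleCounts(x)
  full <- ploidy(x) * ncol(x)
  maf05 <- cc$an == full & cc$an %% 2L == 0L & cc$an > 0L &
    2L * cc$ac == cc$an
  gt <- dosage(x)
  allhet <- maf05 & rowSums(gt != 1L | is.na(gt)) == 0L
  idx <- which(maf05)
  rr <- rowRanges(x)
  list(
    candidates = data.frame(chrom = as.character(seqnames(rr))[idx],
                            pos = start(rr)[idx], allhet = allhet[idx]),
    summary = list(n_maf05 = sum(maf05), n_allhet = sum(allhet),
                   percent_allhet = percentAllHet(sum(allhet), sum(maf05))))
}

#' All-heterozygous percentage among MAF = 0.5 sites
#'
#' @param nAllHet,nMaf05 all-heterozygous and MAF = 0.5 site counts.
#' @return 100 x nAllHet / nMaf05 rounded half-up to 2 decimals (NA when
#'   nMaf05 = 0).
#' @examples
#' percentAllHet(61788, 91835)  # 67.28
#' @export
percentAllHet <- function(nAllHet, nMaf05) {
  if (nMaf05 == 0) return(NA_real_)
  roundHalfUp(100 * nAllHet / nMaf05, 2)
}

#' Cluster all-heterozygous candidate sites into intervals
#'
#' Greedy single-linkage merge along each chromosome: consecutive all-het
#' candidates at most `maxGap` bp apart join one interval; intervals with
#' at least `minSites` members are retained (equivalently, the transitive
#' closure of the <= maxGap relation). Interval bounds are the first and
#' last member positions. Sub-threshold clusters — the dispersed
#' several-hundred-bp micro-clusters typical of this artifact — are
#' returned separately for inspection.
#'
#' @param candidates data.frame from [maf05AllHetSites()] (`candidates`
#'   element); only rows with `allhet = TRUE` are clustered.
#' @param maxGap maximum intra-cluster gap in bp (default 10,000).
#' @param minSites minimum member sites to retain an interval (default 5).
#' @return list: `intervals` (chrom, start, end, n_sites) and
#'   `subthreshold` (same columns, clusters below `minSites`).
#' @export
clusterCandidates <- function(candidates, maxGap = 10000, minSites = 5) {
  cand <- candidates[candidates$allhet, , drop = FALSE]
  rows <- list()
  for (ch in unique(cand$chrom)) {
    p <- sort(cand$pos[cand$chrom == ch])
    if (!length(p)) next
    grp <- cumsum(c(1L, as.integer(diff(p) > maxGap)))
    for (g in unique(grp)) {
      pg <- p[grp == g]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = pg[1], end = pg[length(pg)],
        n_sites = length(pg))
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               n_sites = integer(0))
  keep <- res$n_sites >= minSites
  list(intervals = res[keep, , drop = FALSE],
       subthreshold = res[!keep, , drop = FALSE])
}

#' Depth-ratio test of a candidate duplication interval
#'
#' Compares mean per-sample read depth inside the interval against the
#' median depth of flanking sites (within `flankBp` on either side,
#' interval excluded). A collapsed duplication attracts the reads of both
#' copies, so its depth ratio is near 2; the call is `duplication` when
#' the ratio reaches `minRatio`, else `ambiguous`. With no flanking sites
#' the chromosome-wide median depth is used and the call is additionally
#' marked `ambiguous-flank`.
#'
#' @param interval one-row data.frame (chrom, start, end, n_sites).
#' @param x an [SnvExperiment-class] with a depth assay.
#' @param flankBp flank width in bp (default 50,000).
#' @param minRatio depth ratio calling threshold (default 1.6).
#' @return one-row data.frame: chrom, start, end, n_candidate_sites,
#'   n_region_sites, mean_region_depth, flank_depth, depth_ratio, verdict,
#'   flank_source.
#' @export
depthRatioTest <- function(interval, x, flankBp = 50000, minRatio = 1.6) {
  dp <- readDepth(x)
  if (is.null(dp))
    stop("no depth data: supply per-sample FORMAT DP in the call set")
  chrom <- as.character(seqnames(x))
  pos <- start(rowRanges(x))
  onChrom <- chrom == interval$chrom
  inRegion <- onChrom & pos >= interval$start & pos <= interval$end
  inFlank <- onChrom & !inRegion &
    pos >= interval$start - flankBp & pos <= interval$end + flankBp
  if (!any(inRegion)) stop("interval contains no sites")
  meanRegion <- mean(dp[inRegion, , drop = FALSE], na.rm = TRUE)
  if (any(inFlank)) {
    flankDepth <- median(dp[inFlank, , drop = FALSE], na.rm = TRUE)
    flankSource <- "flank"
  } else {
    flankDepth <- median(dp[onChrom, , drop = FALSE], na.rm = TRUE)
    flankSource <- "chromosome-median"
  }
  ratio <- meanRegion / flankDepth
  verdict <- if (flankSource == "chromosome-median") "ambiguous-flank"
  else if (ratio >= minRatio) "duplication" else "ambiguous"
  data.frame(
    chrom = interval$chrom, start = interval$start, end = interval$end,
    n_candidate_sites = interval$n_sites, n_region_sites = sum(inRegion),
    mean_region_depth = meanRegion, flank_depth = flankDepth,
    depth_ratio = ratio, verdict = verdict, flank_source = flankSource)
}

#' Genome-wide collapsed-duplication scan
#'
#' Pipeline of [maf05AllHetSites()], [clusterCandidates()] and
#' [depthRatioTest()]: flag MAF = 0.5 / all-heterozygous sites, cluster
#' them, and test each cluster's depth against its flanks. Detected sites
#' are flagged, never removed from the call set. Results are deterministic
#' given the input and invariant to sample order.
#'
#' @param x a diploid [SnvExperiment-class] with depth.
#' @param maxGap,minSites see [clusterCandidates()].
#' @param flankBp,minRatio see [depthRatioTest()].
#' @return list: `calls` (data.frame of interval calls sorted by
#'   chromosome and start), `summary` (n_maf05, n_allhet, percent_allhet,
#'   n_subthreshold_clusters), `subthreshold` intervals.
#' @export
dupScan <- function(x, maxGap = 10000, minSites = 5, flankBp = 50000,
                    minRatio = 1.6) {
  cand <- maf05AllHetSites(x)
  cl <- clusterCandidates(cand$candidates, maxGap = maxGap,
                          minSites = minSites)
  calls <- if (nrow(cl$intervals)) do.call(rbind, lapply(
    seq_len(nrow(cl$intervals)), function(i)
      depthRatioTest(cl$intervals[i, ], x, flankBp = flankBp,
                     minRatio = minRatio)))
  else data.frame()
  if (nrow(calls)) {
    calls <- calls[order(match(calls$chrom, seqlevels(x)), calls$start), ]
    rownames(calls) <- NULL
  }
  list(calls = calls,
       summary = c(cand$summary,
                   n_subthreshold_clusters = nrow(cl$subthreshold)),
       subthreshold = cl$subthreshold)
}
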