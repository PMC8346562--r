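#' Apply GATK-style hard-filter expressions to a call set
#'
#' Re-implements the hard-filter recipe used to screen raw SNV calls. Each
#' criterion is evaluated independently; its label is added to the site's
#' FILTER field when the failure expression is true (the expression
#' describes failure, as in GATK VariantFiltration):
#' \describe{
#'   \item{lowDP}{INFO DP < 10}
#'   \item{lowQUAL}{QUAL column < 50}
#'   \item{lowQD}{INFO QD < 1.5}
#'   \item{highSB}{INFO SB > -0.1}
#'   \item{highMQ0}{INFO MQ0 >= 4 and MQ0 / DP > 0.1 (one conjunctive
#'     criterion)}
#'   \item{snpCluster}{the site is one of >= `clusterSize` SNVs whose
#'     positions span at most `window` bp on one chromosome (the upstream
#'     tool's ClusteredSnps convention: a run of `clusterSize` consecutive
#'     sites with last - first <= `window`).}
#' }
#' All comparisons are strict as written, so a site at DP = 10, QUAL = 50,
#' QD = 1.5, SB = -0.1 passes. A criterion whose metric is absent (`NA`) is
#' not applied to that site; each such criterion is logged once. Labels are
#' additive and recomputed from the metrics, so filtering is idempotent.
#'
#' @param x an [SnvExperiment-class] (sites are kept sorted by the class).
#' @param window SNV-cluster window in bp (default 10).
#' @param clusterSize minimum SNVs within the window to fail (default 3).
#' @return `x` with updated FILTER labels; no site is removed.
#' @seealso [passSites()], [filterCounts()]
#' @export
applyFilters <- function(x, window = 10, clusterSize = 3) {
  mc <- mcols(rowRanges(x))
  crit <- list(
    lowDP    = mc$info_dp < 10,
    lowQUAL  = mc$qual < 50,
    lowQD    = mc$info_qd < 1.5,
    highSB   = mc$info_sb > -0.1,
    highMQ0  = mc$info_mq0 >= 4 & (mc$info_mq0 / mc$info_dp) > 0.1,
    snpCluster = snpClusterFlags(as.character(seqnames(x)),
                                 start(rowRanges(x)), window, clusterSize))
  skipped <- names(crit)[vapply(crit, function(f) all(is.na(f)) &&
                                  length(f) > 0, logical(1))]
  if (length(skipped))
    message("applyFilters: metric absent for criterion(s): ",
            paste(skipped, collapse = ", "), " (not applied)")
  labels <- rep("", nrow(x))
  for (nm in names(crit)) {
    f <- !is.na(crit[[nm]]) & crit[[nm]]
    labels[f] <- ifelse(labels[f] == "", nm, paste(labels[f], nm, sep = ";"))
  }
  filterLabels(x) <- labels
  x
}

# Flag SNV-cluster membership: within each chromosome's sorted positions, a
# run of clusterSize consecutive sites spanning <= window bp flags all its
# members.
snpClusterFlags <- function(chrom, pos, window, clusterSize) {
  flag <- logical(length(pos))
  if (clusterSize < 2 || length(pos) < clusterSize) return(flag)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    p <- pos[idx]
    o <- order(p)
    p <- p[o]
    n <- length(p)
    if (n < clusterSize) next
    jmax <- n - clusterSize + 1L
    hit <- p[seq_len(jmax) + clusterSize - 1L] - p[seq_len(jmax)] <= window
    f <- logical(n)
    for (j in which(hit)) f[j:(j + clusterSize - 1L)] <- TRUE
    flag[idx[o]] <- f
  }
  flag
}

#' Subset a call set to passing sites
#'
#' @param x an [SnvExperiment-class] with filters applied.
#' @return the subset of `x` whose FILTER field is empty (PASS), order
#'   preserved.
#' @export
passSites <- function(x) x[filterLabels(x) == "", ]

#' Per-criterion failure counts
#'
#' @param x a filtered [SnvExperiment-class].
#' @return data.frame with columns `criterion` and `n_failed`, plus rows
#'   `PASS` and `total` — both the passing and the removed counts are
#'   exposed, since summaries differ on which one they tabulate.
#' @export
filterCounts <- function(x) {
  fl <- filterLabels(x)
  labs <- unlist(strsplit(fl[fl != ""], ";"))
  tab <- table(labs)
  data.frame(
    criterion = c(names(tab), "PASS", "total"),
    n = c(as.integer(tab), sum(fl == ""), length(fl)),
    row.names = NULL)
}
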