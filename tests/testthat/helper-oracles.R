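# Independent brute-force oracles, deliberately naive (O(n^2) scans and
# per-site loops) so they share no code path with the implementation.

# SNV-cluster membership: flag every site belonging to some set of >=
# clusterSize sites whose positions span <= window bp on one chromosome.
oracleClusterFlags <- function(chrom, pos, window, clusterSize) {
  flag <- logical(length(pos))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    p <- pos[idx]
    for (i in seq_along(p)) {
      for (j in seq_along(p)) {
        lo <- p[i]; hi <- p[j]
        if (hi - lo >= 0 && hi - lo <= window) {
          members <- which(p >= lo & p <= hi)
          if (length(members) >= clusterSize) flag[idx[members]] <- TRUE
        }
      }
    }
  }
  flag
}

# Independent re-evaluation of every hard-filter criterion from a site
# table (as produced by siteTable()).
oracleFilterLabels <- function(st, window = 10, clusterSize = 3) {
  n <- nrow(st)
  lab <- vector("list", n)
  add <- function(i, l) lab[[i]] <<- c(lab[[i]], l)
  clus <- oracleClusterFlags(st$chrom, st$pos, window, clusterSize)
  for (i in seq_len(n)) {
    if (!is.na(st$info_dp[i]) && st$info_dp[i] < 10) add(i, "lowDP")
    if (!is.na(st$qual[i]) && st$qual[i] < 50) add(i, "lowQUAL")
    if (!is.na(st$info_qd[i]) && st$info_qd[i] < 1.5) add(i, "lowQD")
    if (!is.na(st$info_sb[i]) && st$info_sb[i] > -0.1) add(i, "highSB")
    if (!is.na(st$info_mq0[i]) && !is.na(st$info_dp[i]) &&
        st$info_mq0[i] >= 4 && st$info_mq0[i] / st$info_dp[i] > 0.1)
      add(i, "highMQ0")
    if (clus[i]) add(i, "snpCluster")
  }
  vapply(lab, function(l) paste(sort(l), collapse = ";"), character(1))
}

# Window-scan form of the SNV-cluster oracle for larger inputs: a site is
# flagged iff some length-(window+1) position window containing it holds >=
# clusterSize sites. Uses cumulative site counts along the chromosome, so
# it stays independent of the run-based implementation.
oracleClusterFlagsWindow <- function(chrom, pos, window, clusterSize) {
  flag <- logical(length(pos))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    p <- pos[idx]
    len <- max(p) + window + 1L
    present <- integer(len)
    present[p] <- 1L
    cs <- cumsum(present)
    cnt <- function(s) {
      hi <- pmin(s + window, len)
      lo <- pmax(s - 1L, 0L)
      cs[hi] - ifelse(lo == 0L, 0L, cs[lo])
    }
    best <- vapply(p, function(pi) {
      s <- max(1L, pi - window):pi
      max(cnt(s))
    }, numeric(1))
    flag[idx] <- best >= clusterSize
  }
  flag
}

# Vectorized independent re-evaluation of the hard filters (for the
# 10^4-site scale); label sets sorted alphabetically.
oracleFilterLabelsFast <- function(st, window = 10, clusterSize = 3) {
  crit <- cbind(
    highMQ0 = !is.na(st$info_mq0) & !is.na(st$info_dp) & st$info_mq0 >= 4 &
      st$info_mq0 / st$info_dp > 0.1,
    highSB = !is.na(st$info_sb) & st$info_sb > -0.1,
    lowDP = !is.na(st$info_dp) & st$info_dp < 10,
    lowQD = !is.na(st$info_qd) & st$info_qd < 1.5,
    lowQUAL = !is.na(st$qual) & st$qual < 50,
    snpCluster = oracleClusterFlagsWindow(st$chrom, st$pos, window,
                                          clusterSize))
  apply(crit, 1, function(f) paste(colnames(crit)[f], collapse = ";"))
}

# Functional-class assignment by per-site linear scan over the intervals.
oracleAssignClass <- function(chrom, pos, annotation) {
  prec <- c("exon", "utr5", "utr3", "intron", "upstream", "downstream",
            "intergenic")
  ann <- data.frame(chrom = as.character(GenomicRanges::seqnames(annotation)),
                    start = GenomicRanges::start(annotation),
                    end = GenomicRanges::end(annotation),
                    class = S4Vectors::mcols(annotation)$class)
  vapply(seq_along(pos), function(i) {
    hit <- ann$class[ann$chrom == chrom[i] & ann$start <= pos[i] &
                       ann$end >= pos[i]]
    if (!length(hit)) "intergenic" else prec[min(match(hit, prec))]
  }, character(1))
}

# Transitive-closure clustering of positions at gap <= maxGap.
oracleClusterIntervals <- function(chrom, pos, maxGap, minSites) {
  out <- list()
  for (ch in unique(chrom)) {
    p <- sort(pos[chrom == ch])
    assigned <- rep(seq_along(p))
    repeat {
      changed <- FALSE
      for (i in seq_along(p)) for (j in seq_along(p)) {
        if (abs(p[i] - p[j]) <= maxGap && assigned[i] != assigned[j]) {
          assigned[assigned == assigned[j]] <- assigned[i]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    for (g in unique(assigned)) {
      pg <- p[assigned == g]
      if (length(pg) >= minSites)
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = min(pg), end = max(pg), n_sites = length(pg))
    }
  }
  if (length(out)) {
    res <- do.call(rbind, out)
    res[order(res$chrom, res$start), ]
  } else data.frame(chrom = character(0), start = numeric(0),
                    end = numeric(0), n_sites = integer(0))
}

# Jaccard overlap of two 1-based inclusive intervals.
intervalJaccard <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2) + 1)
  uni <- (e1 - s1 + 1) + (e2 - s2 + 1) - inter
  inter / uni
}
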