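#' Simulation parameters for a synthetic population call set
#'
#' Bundles every knob of the population simulator with validity checks. The
#' defaults emulate a 101-horse Thoroughbred resequencing panel at desk
#' scale: 101 diploid samples (2N = 202 alleles), one segregating SNV per
#' 198 bp on average, a neutral 1/i allele-count spectrum, a 2:1
#' transition:transversion ratio, ~20x per-sample coverage, a small set of
#' reference-private (all-ALT-homozygous) sites, and one planted
#' pericentromeric collapsed-duplication region whose pseudo-SNVs are
#' all-heterozygous at twice the baseline depth.
#'
#' @slot nSamples number of diploid samples.
#' @slot chromLengths named numeric vector of chromosome lengths (bp).
#' @slot snvRate expected segregating sites per bp.
#' @slot sfsWeights optional weights over ALT count 1..2N-1; empty means the
#'   neutral shape, weight proportional to 1/i.
#' @slot singletonBoost multiplier applied to the i = 1 class weight.
#' @slot nRefPrivate total reference-private sites, apportioned across
#'   chromosomes by largest remainder (deterministic).
#' @slot dupRegions data.frame with columns chrom, start, end, multiplier:
#'   collapsed-duplication regions whose pseudo-SNV rate is
#'   snvRate x multiplier.
#' @slot tsTvRatio transitions:transversions weight ratio.
#' @slot coverageMean per-sample baseline Poisson depth.
#' @slot failFraction fraction of sites drawn to fail each hard-filter
#'   criterion independently.
#' @slot seed master integer seed; per-chromosome substreams are derived
#'   from it so chromosome output is stable under chromosome subsetting.
#' @export
setClass("SimParams", representation(
  nSamples = "integer", chromLengths = "numeric", snvRate = "numeric",
  sfsWeights = "numeric", singletonBoost = "numeric", nRefPrivate = "integer",
  dupRegions = "data.frame", tsTvRatio = "numeric", coverageMean = "numeric",
  failFraction = "numeric", seed = "integer"))

setValidity("SimParams", function(object) {
  msg <- character(0)
  if (object@nSamples < 1L) msg <- c(msg, "nSamples must be >= 1")
  if (is.null(names(object@chromLengths)) || any(object@chromLengths <= 0))
    msg <- c(msg, "chromLengths must be a named vector of positive lengths")
  if (object@snvRate <= 0) msg <- c(msg, "snvRate must be > 0")
  if (object@tsTvRatio <= 0) msg <- c(msg, "tsTvRatio must be > 0")
  if (object@coverageMean <= 0) msg <- c(msg, "coverageMean must be > 0")
  if (object@singletonBoost <= 0) msg <- c(msg, "singletonBoost must be > 0")
  if (object@failFraction < 0 || object@failFraction >= 1)
    msg <- c(msg, "failFraction must be in [0, 1)")
  if (length(object@sfsWeights) && any(object@sfsWeights < 0))
    msg <- c(msg, "sfsWeights must be non-negative")
  dr <- object@dupRegions
  if (nrow(dr)) {
    if (!all(c("chrom", "start", "end", "multiplier") %in% names(dr)))
      msg <- c(msg, "dupRegions needs columns chrom, start, end, multiplier")
    else {
      if (!all(dr$chrom %in% names(object@chromLengths)))
        msg <- c(msg, "dupRegions on unknown chromosomes")
      else if (any(dr$start < 1 | dr$end > object@chromLengths[dr$chrom]))
        msg <- c(msg, "dupRegions outside chromosome bounds")
      if (any(dr$start > dr$end)) msg <- c(msg, "dupRegions start > end")
      if (any(dr$multiplier <= 0)) msg <- c(msg, "dup multiplier must be > 0")
      for (ch in unique(dr$chrom)) {
        d <- dr[dr$chrom == ch, , drop = FALSE]
        d <- d[order(d$start), , drop = FALSE]
        if (nrow(d) > 1 && any(d$start[-1] <= d$end[-nrow(d)]))
          msg <- c(msg, "dupRegions overlap on the same chromosome")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Scaled-down default genome: four autosomes and an X, 20 Mb total
#'
#' Chromosome names follow the equine convention (ECA); ECA29 carries the
#' default planted pericentromeric duplication.
#' @return named numeric vector of chromosome lengths (bp).
#' @export
defaultChromLengths <- function() {
  c(ECA1 = 6e6, ECA2 = 5e6, ECA3 = 4e6, ECA29 = 3e6, ECAX = 2e6)
}

#' @rdname SimParams-class
#' @param nSamples,chromLengths,snvRate,sfsWeights,singletonBoost,nRefPrivate,dupRegions,tsTvRatio,coverageMean,failFraction,seed see slots.
#' @export
simParams <- function(nSamples = 101L,
                      chromLengths = defaultChromLengths(),
                      snvRate = 1 / 198,
                      sfsWeights = numeric(0),
                      singletonBoost = 1,
                      nRefPrivate = 30L,
                      dupRegions = data.frame(chrom = "ECA29", start = 1L,
                                              end = 200000L, multiplier = 2),
                      tsTvRatio = 2,
                      coverageMean = 20,
                      failFraction = 0.05,
                      seed = 1L) {
  new("SimParams", nSamples = as.integer(nSamples),
      chromLengths = chromLengths, snvRate = snvRate,
      sfsWeights = as.numeric(sfsWeights), singletonBoost = singletonBoost,
      nRefPrivate = as.integer(nRefPrivate), dupRegions = dupRegions,
      tsTvRatio = tsTvRatio, coverageMean = coverageMean,
      failFraction = failFraction, seed = as.integer(seed))
}

#' Normalized allele-count spectrum weights
#'
#' Weights over ALT-allele count i = 1..2N-1 used to draw each segregating
#' site's count. Default is the neutral shape (weight proportional to 1/i)
#' with an optional multiplier on the singleton class; custom weights
#' override the shape before the boost is applied.
#'
#' @param params a [SimParams-class] object.
#' @return numeric vector of length 2N-1 summing to 1.
#' @export
sfsShapeWeights <- function(params) {
  nAllele <- 2L * params@nSamples
  w <- params@sfsWeights
  if (!length(w)) w <- 1 / seq_len(nAllele - 1L)
  if (length(w) != nAllele - 1L)
    stop("sfsWeights must have length 2N-1 = ", nAllele - 1L)
  w[1] <- w[1] * params@singletonBoost
  w / sum(w)
}

# Birth-year distribution of the emulated 101-horse panel (years with the
# number of horses born in each). Sampled proportionally when nSamples
# differs from 101.
birthYearWeights <- function() {
  c(`1985` = 1, `1990` = 1, `1993` = 1, `1994` = 1, `1996` = 1, `1998` = 1,
    `1999` = 3, `2000` = 1, `2001` = 1, `2002` = 1, `2007` = 5, `2008` = 2,
    `2010` = 2, `2011` = 1, `2012` = 4, `2013` = 18, `2014` = 20,
    `2015` = 21, `2016` = 16)
}

# Largest-remainder apportionment of a total across chromosomes by length;
# deterministic so the ref-private count is exact and per-chromosome output
# does not depend on other chromosomes' RNG streams.
apportionByLength <- function(total, lengths) {
  if (total == 0L) return(setNames(integer(length(lengths)), names(lengths)))
  q <- total * lengths / sum(lengths)
  n <- floor(q)
  rem <- total - sum(n)
  if (rem > 0) {
    ord <- order(q - n, decreasing = TRUE)
    n[ord[seq_len(rem)]] <- n[ord[seq_len(rem)]] + 1
  }
  setNames(as.integer(n), names(lengths))
}

# Draw ALT bases for REF bases under a transitions:transversions weight
# ratio; transversion target chosen uniformly between the two options.
drawAltBases <- function(ref, tsTvRatio) {
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  tvOptions <- list(A = c("C", "T"), G = c("C", "T"),
                    C = c("A", "G"), T = c("A", "G"))
  isTs <- runif(length(ref)) < tsTvRatio / (tsTvRatio + 1)
  alt <- transition[ref]
  if (any(!isTs)) {
    pick <- runif(sum(!isTs)) < 0.5
    alt[!isTs] <- mapply(function(r, p) tvOptions[[r]][1 + p],
                         ref[!isTs], pick)
  }
  unname(alt)
}

# Draw site QUAL/INFO metrics so that, independently per criterion, a
# failFraction share of sites violates it. Values are rounded half-up to 2
# decimals at generation time so VCF round-trips are exact. Draw ranges
# leave a margin around each threshold so rounding never flips pass/fail.
drawSiteMetrics <- function(n, meanInfoDp, failFraction) {
  failDraw <- function(lo, hi) roundHalfUp(runif(n, lo, hi), 2)
  fails <- function() runif(n) < failFraction
  qual <- ifelse(fails(), failDraw(10, 49.4), failDraw(51, 2000))
  dp <- ifelse(fails(), sample(1:9, n, replace = TRUE),
               pmax(10, rpois(n, meanInfoDp)))
  qd <- ifelse(fails(), failDraw(0.01, 1.44), failDraw(2, 35))
  sb <- ifelse(fails(), failDraw(-0.08, 5), failDraw(-40, -0.5))
  mq0 <- ifelse(fails(), pmax(4, ceiling(0.1 * dp) + 1),
                sample(0:3, n, replace = TRUE))
  list(qual = qual, dp = as.integer(dp), qd = qd, mq0 = as.integer(mq0), sb = sb)
}

#' Simulate a multi-sample population SNV call set with ground truth
#'
#' Generates a diploid call set of three site classes, recorded in a truth
#' ledger:
#' \describe{
#'   \item{segregating}{an ALT count k is drawn from the spectrum weights
#'     and exactly k ALT alleles are placed on the 2N haplotypes by uniform
#'     permutation, so the realized spectrum equals the drawn multiset
#'     exactly; the carrier of every k = 1 site is recorded.}
#'   \item{ref_private}{sites where every sample is ALT-homozygous,
#'     emulating alleles private to the reference individual.}
#'   \item{dup_artifact}{collapsed-duplication pseudo-SNVs inside the
#'     planted regions: every genotype heterozygous (MAF = 0.5) and
#'     per-sample depth Poisson with mean twice the baseline.}
#' }
#' Per-site QUAL/INFO metrics are drawn so that about `failFraction` of
#' sites violates each hard-filter criterion independently. Sites in exons
#' of the deterministic tiled annotation receive planted coding impacts.
#' Fully deterministic under a fixed seed, with independent per-chromosome
#' substreams.
#'
#' @param params a [SimParams-class] object.
#' @param annotation optional functional annotation `GRanges` (default:
#'   [generateAnnotation()] on the params' chromosomes).
#' @return list with elements `calls` (an [SnvExperiment-class]),
#'   `annotation` (GRanges), and `ledger` (truth ledger list with
#'   `site_class`, `singleton_carrier`, `dup_truth`, `impact_truth`).
#' @examples
#' sim <- simulatePopulation(simParams(nSamples = 6L,
#'   chromLengths = c(chr1 = 2e5), nRefPrivate = 4L,
#'   dupRegions = data.frame(chrom = "chr1", start = 1, end = 5e4,
#'                           multiplier = 3), seed = 7L))
#' table(sim$ledger$site_class$class)
#' @export
simulatePopulation <- function(params, annotation = NULL) {
  validObject(params)
  nS <- params@nSamples
  nAllele <- 2L * nS
  if (is.null(annotation)) annotation <- generateAnnotation(params@chromLengths)
  w <- sfsShapeWeights(params)
  refPrivByChrom <- apportionByLength(params@nRefPrivate, params@chromLengths)

  set.seed(streamSeed(params@seed, "samples"))
  yw <- birthYearWeights()
  # at the emulated panel size the birth-year distribution is reproduced
  # exactly; other sizes sample years proportionally
  years <- if (nS == sum(yw)) sample(rep(names(yw), yw)) else
    sample(names(yw), nS, replace = TRUE, prob = yw)
  meta <- data.frame(
    sample_id = sprintf("TB%03d", seq_len(nS)),
    sex = sample(c("F", "M"), nS, replace = TRUE),
    birth_year = as.integer(years),
    founder = sprintf("FM%02d", 1L + (seq_len(nS) - 1L) %% 10L))

  perChrom <- lapply(names(params@chromLengths), function(ch) {
    len <- params@chromLengths[[ch]]
    set.seed(streamSeed(params@seed, ch))
    dr <- params@dupRegions[params@dupRegions$chrom == ch, , drop = FALSE]
    dupPos <- integer(0)
    if (nrow(dr)) {
      for (i in seq_len(nrow(dr))) {
        wid <- dr$end[i] - dr$start[i] + 1
        nd <- rpois(1, params@snvRate * dr$multiplier[i] * wid)
        p <- as.integer(dr$start[i]) - 1L +
          sampleDistinctPositions(wid, nd, what = "dup-artifact sites")
        dupPos <- c(dupPos, p)
      }
    }
    nSeg <- rpois(1, params@snvRate * len)
    nPriv <- refPrivByChrom[[ch]]
    other <- sampleDistinctPositions(len, nSeg + nPriv, exclude = dupPos)
    segPos <- other[seq_len(nSeg)]
    privPos <- other[nSeg + seq_len(nPriv)]

    pos <- c(segPos, privPos, dupPos)
    cls <- rep(c("segregating", "ref_private", "dup_artifact"),
               c(nSeg, nPriv, length(dupPos)))
    n <- length(pos)

    gt <- matrix(0L, nrow = n, ncol = nS)
    carrier <- rep(NA_character_, n)
    kDrawn <- rep(NA_integer_, n)
    if (nSeg > 0) {
      k <- sample.int(nAllele - 1L, nSeg, replace = TRUE, prob = w)
      kDrawn[seq_len(nSeg)] <- k
      for (i in seq_len(nSeg)) {
        hap <- sample.int(nAllele, k[i])
        gt[i, ] <- tabulate((hap + 1L) %/% 2L, nbins = nS)
      }
      singles <- which(k == 1L)
      carrier[singles] <- meta$sample_id[
        apply(gt[singles, , drop = FALSE] == 1L, 1, which)]
    }
    if (nPriv > 0) gt[nSeg + seq_len(nPriv), ] <- 2L
    if (length(dupPos)) gt[nSeg + nPriv + seq_len(length(dupPos)), ] <- 1L

    lam <- rep(params@coverageMean, n)
    lam[cls == "dup_artifact"] <- 2 * params@coverageMean
    depth <- matrix(rpois(n * nS, rep(lam, nS)), nrow = n)

    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt <- drawAltBases(ref, params@tsTvRatio)
    mdp <- nS * params@coverageMean * ifelse(cls == "dup_artifact", 2, 1)
    met <- drawSiteMetrics(n, mdp, params@failFraction)

    ord <- order(pos)
    list(chrom = rep(ch, n), pos = pos[ord], cls = cls[ord],
         gt = gt[ord, , drop = FALSE], depth = depth[ord, , drop = FALSE],
         ref = ref[ord], alt = alt[ord], carrier = carrier[ord],
         k = kDrawn[ord],
         met = lapply(met, function(v) v[ord]))
  })

  cat2 <- function(f) do.call(c, lapply(perChrom, `[[`, f))
  gt <- do.call(rbind, lapply(perChrom, `[[`, "gt"))
  depth <- do.call(rbind, lapply(perChrom, `[[`, "depth"))
  met <- lapply(c("qual", "dp", "qd", "mq0", "sb"),
                function(f) do.call(c, lapply(perChrom, function(p) p$met[[f]])))
  names(met) <- c("qual", "dp", "qd", "mq0", "sb")

  x <- SnvExperiment(
    chrom = cat2("chrom"), pos = cat2("pos"), ref = cat2("ref"),
    alt = cat2("alt"), gt = gt, depth = depth, sampleData = meta,
    chromLengths = params@chromLengths, qual = met$qual,
    info = list(dp = met$dp, qd = met$qd, mq0 = met$mq0, sb = met$sb))

  # functional classes are deterministic given the annotation; coding
  # impacts are planted on exonic sites and recorded in the ledger
  cls <- assignFunctionalClass(rowRanges(x), annotation)
  mcols(rowRanges(x))$ann_class <- as.character(cls)
  exonIdx <- which(cls == "exon")
  set.seed(streamSeed(params@seed, "impacts"))
  impacts <- c("synonymous", "non_synonymous", "start_gained", "start_lost",
               "stop_gained", "stop_lost", "other")
  if (length(exonIdx)) {
    mcols(rowRanges(x))$ann_impact[exonIdx] <- sample(
      impacts, length(exonIdx), replace = TRUE,
      prob = c(0.55, 0.40, 0.01, 0.01, 0.01, 0.01, 0.01))
  }

  st <- siteTable(x)
  siteClass <- data.frame(chrom = cat2("chrom"), pos = cat2("pos"),
                          class = cat2("cls"), k = cat2("k"))
  siteClass <- siteClass[order(match(siteClass$chrom, names(params@chromLengths)),
                               siteClass$pos), ]
  rownames(siteClass) <- NULL
  carrier <- data.frame(chrom = cat2("chrom"), pos = cat2("pos"),
                        sample_id = cat2("carrier"))
  carrier <- carrier[!is.na(carrier$sample_id), ]
  carrier <- carrier[order(match(carrier$chrom, names(params@chromLengths)),
                           carrier$pos), ]
  rownames(carrier) <- NULL
  ledger <- list(
    site_class = siteClass,
    singleton_carrier = carrier,
    dup_truth = params@dupRegions,
    impact_truth = st[!is.na(st$ann_impact),
                      c("chrom", "pos", "ann_impact")],
    seed = params@seed)
  list(calls = x, annotation = annotation, ledger = ledger)
}

#' Simulate haploid mitochondrial haplotypes structured by founder mares
#'
#' Builds `nFounders` distinct founder haplotypes over `nMitoSites` variable
#' positions on a fixed 16,660 bp mitochondrial genome. Each sample inherits
#' its founder's haplotype plus Poisson(`lambda`) private mutations. A
#' fraction `errorRate` of samples is silently given a haplotype from a
#' different founder while keeping the recorded founder label — the injected
#' pedigree errors the concordance analysis must flag.
#'
#' @param params a [SimParams-class] (supplies nSamples, coverage, seed).
#' @param nFounders number of founder mares (>= 2 when errors are injected).
#' @param nMitoSites number of variable positions (<= 16,660).
#' @param errorRate fraction of samples with an injected wrong-lineage
#'   haplotype.
#' @param lambda mean number of private mutations per sample.
#' @return list with `calls` (haploid [SnvExperiment-class]) and `ledger`
#'   (list with `mito_lineage`: recorded and true founder per sample;
#'   `mito_errors`: sample ids with injected errors).
#' @export
simulateMito <- function(params, nFounders = 10L, nMitoSites = 60L,
                         errorRate = 0.02, lambda = 0.3) {
  validObject(params)
  mtLen <- 16660L
  if (nMitoSites > mtLen)
    stop("nMitoSites exceeds the mitochondrial genome length (16,660 bp)")
  if (nFounders < 1L) stop("nFounders must be >= 1")
  nS <- params@nSamples
  set.seed(streamSeed(params@seed, "MT"))

  pos <- sort(sample.int(mtLen, nMitoSites))
  ref <- sample(c("A", "C", "G", "T"), nMitoSites, replace = TRUE)
  alt <- drawAltBases(ref, params@tsTvRatio)

  founderHap <- matrix(rbinom(nFounders * nMitoSites, 1L, 0.5),
                       nrow = nFounders)
  while (anyDuplicated(founderHap) > 0) {
    dup <- which(duplicated(founderHap))
    founderHap[dup, ] <- rbinom(length(dup) * nMitoSites, 1L, 0.5)
  }
  founderIds <- sprintf("FM%02d", seq_len(nFounders))

  trueFounder <- sample.int(nFounders, nS, replace = TRUE)
  recorded <- trueFounder
  nErr <- round(errorRate * nS)
  errSamples <- integer(0)
  if (nErr > 0) {
    if (nFounders < 2L) stop("injecting pedigree errors needs >= 2 founders")
    errSamples <- sample.int(nS, nErr)
    for (s in errSamples) {
      trueFounder[s] <- sample(setdiff(seq_len(nFounders), recorded[s]), 1)
    }
  }

  gt <- founderHap[trueFounder, , drop = FALSE]
  nMut <- rpois(nS, lambda)
  for (s in which(nMut > 0)) {
    flip <- sample.int(nMitoSites, min(nMut[s], nMitoSites))
    gt[s, flip] <- 1L - gt[s, flip]
  }

  meta <- data.frame(
    sample_id = sprintf("TB%03d", seq_len(nS)),
    sex = NA_character_, birth_year = NA_integer_,
    founder = founderIds[recorded])
  depth <- matrix(rpois(nMitoSites * nS, params@coverageMean),
                  nrow = nMitoSites)
  met <- drawSiteMetrics(nMitoSites, nS * params@coverageMean,
                         params@failFraction)
  calls <- SnvExperiment(
    chrom = rep("MT", nMitoSites), pos = pos, ref = ref, alt = alt,
    gt = t(gt), depth = depth, sampleData = meta,
    chromLengths = c(MT = mtLen), qual = met$qual,
    info = list(dp = met$dp, qd = met$qd, mq0 = met$mq0, sb = met$sb),
    ploidy = 1L)
  ledger <- list(
    mito_lineage = data.frame(sample_id = meta$sample_id,
                              recorded_founder = founderIds[recorded],
                              true_founder = founderIds[trueFounder]),
    mito_errors = sort(meta$sample_id[errSamples]),
    founder_haplotypes = founderHap,
    seed = params@seed)
  list(calls = calls, ledger = ledger)
}
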