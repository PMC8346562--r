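test_that("reference-private sites are all-ALT-homozygous and exactly counted", {
  sim <- smallSim(seed = 3L)
  led <- sim$ledger$site_class
  rp <- led[led$class == "ref_private", ]
  expect_identical(nrow(rp), 8L)
  st <- siteTable(sim$calls)
  idx <- match(paste(rp$chrom, rp$pos), paste(st$chrom, st$pos))
  gt <- dosage(sim$calls)[idx, , drop = FALSE]
  expect_true(all(gt == 2L))
})

test_that("dup-artifact sites are all-heterozygous, hence MAF exactly 0.5", {
  sim <- smallSim(seed = 5L)
  led <- sim$ledger$site_class
  dup <- led[led$class == "dup_artifact", ]
  expect_gt(nrow(dup), 0)
  st <- siteTable(sim$calls)
  idx <- match(paste(dup$chrom, dup$pos), paste(st$chrom, st$pos))
  gt <- dosage(sim$calls)[idx, , drop = FALSE]
  expect_true(all(gt == 1L))
  cc <- alleleCounts(sim$calls)[idx, ]
  expect_true(all(cc$ac * 2L == cc$an))
  expect_true(all(dup$pos >= 50001 & dup$pos <= 90000))
})

test_that("singleton share matches the normalized neutral weight of the i=1 class", {
  # independent oracle: the exact normalized weight by direct summation
  p <- simParams(nSamples = 101L, chromLengths = c(ECA1 = 5e6),
                 nRefPrivate = 0L, dupRegions = data.frame(
                   chrom = character(0), start = numeric(0),
                   end = numeric(0), multiplier = numeric(0)),
                 seed = 17L)
  w1 <- (1 / 1) / sum(1 / seq_len(201))
  expect_equal(w1, sfsShapeWeights(p)[1])
  sim <- simulatePopulation(p)
  led <- sim$ledger$site_class
  n <- sum(led$class == "segregating")
  obs <- sum(led$k == 1L, na.rm = TRUE) / n
  se <- sqrt(w1 * (1 - w1) / n)
  expect_lt(abs(obs - w1), 3 * se)
  # exact-assignment design: realized ALT count equals the drawn count
  cc <- alleleCounts(sim$calls)
  expected <- ifelse(led$class == "segregating", led$k,
                     ifelse(led$class == "ref_private", 202L, 101L))
  expect_identical(cc$ac, as.integer(expected))
})

test_that("fixed seed gives byte-identical call sets, VCFs and ledgers", {
  s1 <- smallSim(seed = 9L)
  s2 <- smallSim(seed = 9L)
  expect_identical(dosage(s1$calls), dosage(s2$calls))
  expect_identical(siteTable(s1$calls), siteTable(s2$calls))
  expect_identical(s1$ledger, s2$ledger)
  f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
  writeSnvVcf(s1$calls, f1); writeSnvVcf(s2$calls, f2)
  expect_identical(readLines(f1), readLines(f2))
  l1 <- tempfile(fileext = ".json")
  writeTruthLedger(s1$ledger, l1)
  led <- readTruthLedger(l1)
  expect_equal(led$site_class, s1$ledger$site_class)
  expect_equal(led$singleton_carrier, s1$ledger$singleton_carrier)
})

test_that("per-chromosome output is stable under chromosome subsetting", {
  pAll <- smallParams(seed = 21L)
  pOne <- simParams(nSamples = 12L, chromLengths = c(ECA2 = 3e5),
                    nRefPrivate = 0L,
                    dupRegions = data.frame(chrom = character(0),
                                            start = numeric(0), end = numeric(0),
                                            multiplier = numeric(0)),
                    seed = 21L)
  simAll <- simulatePopulation(pAll)
  simOne <- simulatePopulation(pOne)
  segAll <- simAll$ledger$site_class
  segOne <- simOne$ledger$site_class
  posAll <- sort(segAll$pos[segAll$chrom == "ECA2" & segAll$class == "segregating"])
  posOne <- sort(segOne$pos[segOne$class == "segregating"])
  # the ECA2 stream depends only on the master seed and the chromosome
  # name, so its segregating positions are unchanged when the other
  # chromosomes are dropped
  expect_identical(posOne, posAll)
})

test_that("site classes ledger round-trips the call set exactly", {
  sim <- smallSim(seed = 13L)
  st <- siteTable(sim$calls)
  led <- sim$ledger$site_class
  expect_identical(nrow(st), nrow(led))
  expect_identical(paste(st$chrom, st$pos), paste(led$chrom, led$pos))
  expect_false(any(duplicated(paste(led$chrom, led$pos))))
})

test_that("impossible site loads raise a chromosome-overflow error", {
  p <- simParams(nSamples = 4L, chromLengths = c(tiny = 50),
                 snvRate = 3, nRefPrivate = 0L,
                 dupRegions = data.frame(chrom = character(0),
                                         start = numeric(0), end = numeric(0),
                                         multiplier = numeric(0)),
                 seed = 2L)
  expect_error(simulatePopulation(p), "overflow")
})

test_that("the emulated panel's birth-year distribution is reproduced at n = 101", {
  p <- simParams(nSamples = 101L, chromLengths = c(ECA1 = 2e5), seed = 30L,
                 dupRegions = data.frame(chrom = character(0),
                                         start = numeric(0), end = numeric(0),
                                         multiplier = numeric(0)))
  sim <- simulatePopulation(p)
  meta <- sampleMeta(sim$calls)
  tab <- table(meta$birth_year)
  expect_identical(as.integer(tab[["2015"]]), 21L)
  expect_identical(as.integer(tab[["1985"]]), 1L)
  expect_identical(sum(tab), 101L)
})

test_that("mitochondrial simulation honours noise-free and error-free settings", {
  p <- smallParams(seed = 7L)
  m <- simulateMito(p, nFounders = 3L, nMitoSites = 40L, errorRate = 0,
                    lambda = 0)
  haps <- buildHaplotypes(m$calls)
  lin <- m$ledger$mito_lineage
  expect_identical(lin$recorded_founder, lin$true_founder)
  expect_identical(m$ledger$mito_errors, character(0))
  fh <- m$ledger$founder_haplotypes
  for (i in seq_len(nrow(lin))) {
    fidx <- as.integer(sub("FM", "", lin$true_founder[i]))
    expect_identical(unname(haps$alleles[lin$sample_id[i], ]),
                     unname(fh[fidx, ]))
  }
})

test_that("an injected pedigree error sits far from its recorded founder line", {
  p <- simParams(nSamples = 20L, chromLengths = c(ECA1 = 2e5), seed = 4L,
                 dupRegions = data.frame(chrom = character(0),
                                         start = numeric(0), end = numeric(0),
                                         multiplier = numeric(0)))
  m <- simulateMito(p, nFounders = 2L, nMitoSites = 60L, errorRate = 0.05,
                    lambda = 0.3)
  err <- m$ledger$mito_errors
  expect_gt(length(err), 0)
  lin <- m$ledger$mito_lineage
  fh <- m$ledger$founder_haplotypes
  nDiff <- sum(fh[1, ] != fh[2, ])
  haps <- buildHaplotypes(m$calls)
  for (s in err) {
    rec <- as.integer(sub("FM", "", lin$recorded_founder[lin$sample_id == s]))
    d <- sum(haps$alleles[s, ] != fh[rec, ])
    expect_gte(d, nDiff - 3)  # founder distance minus private mutations
  }
})

test_that("mito site count beyond the 16,660 bp genome is rejected and seeds reproduce", {
  p <- smallParams(seed = 8L)
  expect_error(simulateMito(p, nMitoSites = 20000L), "16,660")
  m1 <- simulateMito(p); m2 <- simulateMito(p)
  expect_identical(dosage(m1$calls), dosage(m2$calls))
  expect_identical(m1$ledger$mito_lineage, m2$ledger$mito_lineage)
})

test_that("annotation tiling partitions each chromosome after precedence", {
  len <- c(chrA = 1e6)
  annEmpty <- generateAnnotation(len, geneStarts = list(chrA = numeric(0)))
  expect_identical(length(annEmpty), 1L)
  expect_identical(S4Vectors::mcols(annEmpty)$class, "intergenic")
  expect_identical(GenomicRanges::start(annEmpty), 1L)
  expect_identical(GenomicRanges::end(annEmpty), 1000000L)

  ann <- generateAnnotation(c(chrA = 5e5))
  cov <- GenomicRanges::reduce(ann, ignore.strand = TRUE)
  expect_identical(length(cov), 1L)
  expect_identical(GenomicRanges::width(cov), 500000L)
})

test_that("flank coordinate arithmetic: 5 kb upstream ends just before the gene", {
  ann <- generateAnnotation(c(chrA = 1e6), geneStarts = list(chrA = 100001))
  up <- ann[S4Vectors::mcols(ann)$class == "upstream"]
  expect_identical(GenomicRanges::start(up), 95001L)
  expect_identical(GenomicRanges::end(up), 100000L)
})

test_that("annotation BED round-trips through 0-based half-open coordinates", {
  len <- c(chrA = 2e5)
  ann <- generateAnnotation(len)
  path <- tempfile(fileext = ".bed")
  writeAnnotationBed(ann, path)
  back <- readAnnotationBed(path, chromLengths = len)
  expect_identical(GenomicRanges::start(back), GenomicRanges::start(ann))
  expect_identical(GenomicRanges::end(back), GenomicRanges::end(ann))
  expect_identical(S4Vectors::mcols(back)$class, S4Vectors::mcols(ann)$class)
})
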