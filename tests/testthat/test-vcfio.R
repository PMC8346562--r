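writeTempVcf <- function(lines) {
  path <- tempfile(fileext = ".vcf")
  writeLines(lines, path)
  path
}

miniHeader <- c(
  "##fileformat=VCFv4.2",
  "##contig=<ID=ECA1,length=1000000>",
  "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
  "##INFO=<ID=QD,Number=1,Type=Float,Description=\"q\">",
  "##INFO=<ID=MQ0,Number=1,Type=Integer,Description=\"m\">",
  "##INFO=<ID=SB,Number=1,Type=Float,Description=\"s\">",
  "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
  "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
  paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3"), collapse = "\t"))

test_that("GT strings become ALT dosages and missing calls become NA", {
  path <- writeTempVcf(c(miniHeader,
    "ECA1\t100\t.\tA\tG\t99\tPASS\tDP=60\tGT:DP\t0/1:20\t0/0:18\t0/0:22",
    "ECA1\t200\t.\tC\tT\t80\tPASS\tDP=55\tGT:DP\t./.:0\t1/1:19\t0|1:21"))
  x <- readSnvVcf(path)
  expect_identical(unname(dosage(x)),
                   matrix(c(1L, NA, 0L, 2L, 0L, 1L), nrow = 2))
  expect_identical(unname(readDepth(x)[1, ]), c(20L, 18L, 22L))
  expect_identical(attr(x, "n_skipped"), 0L)
})

test_that("multi-allelic and indel records are skipped with a count", {
  path <- writeTempVcf(c(miniHeader,
    "ECA1\t100\t.\tA\tG\t99\tPASS\tDP=60\tGT\t0/1\t0/0\t0/0",
    "ECA1\t200\t.\tC\tT,A\t80\tPASS\tDP=55\tGT\t0/1\t0/0\t1/2",
    "ECA1\t300\t.\tG\tGA\t70\tPASS\tDP=50\tGT\t0/1\t0/0\t0/0"))
  expect_message(x <- readSnvVcf(path), "skipped 2")
  expect_identical(nrow(x), 1L)
  expect_identical(attr(x, "n_skipped"), 2L)
})

test_that("write then read round-trips sites, dosages, depth and FILTER", {
  sim <- smallSim(seed = 31L)
  x <- applyFilters(sim$calls)
  path <- tempfile(fileext = ".vcf")
  writeSnvVcf(x, path)
  y <- readSnvVcf(path)
  cols <- c("chrom", "pos", "ref", "alt", "qual", "info_dp", "info_qd",
            "info_mq0", "info_sb", "filter")
  expect_identical(siteTable(y)[cols], siteTable(x)[cols])
  expect_identical(unname(dosage(y)), unname(dosage(x)))
  expect_identical(unname(readDepth(y)), unname(readDepth(x)))
  expect_identical(colnames(y), colnames(x))
})

test_that("an empty call set writes a header-only VCF that reads back empty", {
  sim <- smallSim(seed = 31L)
  x <- sim$calls[integer(0), ]
  path <- tempfile(fileext = ".vcf")
  writeSnvVcf(x, path)
  lines <- readLines(path)
  expect_true(all(startsWith(lines, "#")))
  y <- readSnvVcf(path)
  expect_identical(nrow(y), 0L)
})

test_that("unsorted construction comes out sorted by chromosome and position", {
  x <- SnvExperiment(chrom = c("ECA2", "ECA1", "ECA1"), pos = c(5, 300, 10),
                     ref = c("A", "C", "G"), alt = c("G", "T", "A"),
                     gt = matrix(0L, 3, 2),
                     chromLengths = c(ECA1 = 1000, ECA2 = 1000))
  st <- siteTable(x)
  expect_identical(st$chrom, c("ECA1", "ECA1", "ECA2"))
  expect_identical(st$pos, c(10L, 300L, 5L))
})

test_that("each hard-filter criterion labels exactly its failing sites", {
  mk <- function(qual, dp, qd, mq0, sb) {
    SnvExperiment(chrom = "ECA1", pos = 1000, ref = "A", alt = "G",
                  gt = matrix(1L, 1, 2), qual = qual,
                  info = list(dp = dp, qd = qd, mq0 = mq0, sb = sb))
  }
  lowdp <- applyFilters(mk(99, 9, 12, 0, -20))
  expect_identical(filterLabels(lowdp), "lowDP")
  # boundary values pass: every comparison is strict
  boundary <- applyFilters(mk(50, 10, 1.5, 0, -0.1))
  expect_identical(filterLabels(boundary), "")
  # MQ0 is a single conjunctive criterion: MQ0 >= 4 alone is not enough
  mq0only <- applyFilters(mk(99, 60, 12, 5, -20))
  expect_identical(filterLabels(mq0only), "")
  mq0both <- applyFilters(mk(99, 30, 12, 5, -20))
  expect_identical(filterLabels(mq0both), "highMQ0")
})

test_that("SNV clusters are flagged per the 10 bp / 3-SNV window rule", {
  mk <- function(pos) {
    SnvExperiment(chrom = "ECA1", pos = pos, ref = "A", alt = "G",
                  gt = matrix(1L, length(pos), 2), qual = 99,
                  info = list(dp = 60, qd = 12, mq0 = 0, sb = -20))
  }
  close3 <- applyFilters(mk(c(100, 105, 109)))
  expect_identical(filterLabels(close3), rep("snpCluster", 3))
  spread <- applyFilters(mk(c(100, 105, 120)))
  expect_identical(filterLabels(spread), rep("", 3))
})

test_that("filter evaluation matches the brute-force oracle and is idempotent", {
  sim <- simulatePopulation(simParams(
    nSamples = 8L, chromLengths = c(ECA1 = 2e5, ECA2 = 1e5),
    nRefPrivate = 3L, failFraction = 0.15,
    dupRegions = data.frame(chrom = character(0), start = numeric(0),
                            end = numeric(0), multiplier = numeric(0)),
    seed = 41L))
  x1 <- applyFilters(sim$calls)
  x2 <- applyFilters(x1)
  expect_identical(filterLabels(x1), filterLabels(x2))
  got <- vapply(strsplit(filterLabels(x1), ";"),
                function(l) paste(sort(l), collapse = ";"), character(1))
  expect_identical(got, oracleFilterLabels(siteTable(x1)))
})

test_that("absent metrics disable their criterion with a log message", {
  x <- SnvExperiment(chrom = "ECA1", pos = c(100, 2000), ref = "A", alt = "G",
                     gt = matrix(1L, 2, 2), qual = c(99, 10),
                     info = list(dp = c(60, 60), qd = c(12, 12),
                                 mq0 = c(0, 0), sb = NA))
  expect_message(xf <- applyFilters(x), "highSB")
  expect_identical(filterLabels(xf), c("", "lowQUAL"))
})

test_that("passSites is an order-preserving subset and counts reconcile", {
  sim <- smallSim(seed = 43L)
  x <- applyFilters(sim$calls)
  p <- passSites(x)
  expect_true(all(filterLabels(p) == ""))
  expect_lte(nrow(p), nrow(x))
  stx <- siteTable(x); stp <- siteTable(p)
  keys <- paste(stx$chrom, stx$pos)[stx$filter == ""]
  expect_identical(paste(stp$chrom, stp$pos), keys)
  fc <- filterCounts(x)
  expect_identical(fc$n[fc$criterion == "PASS"], nrow(p))
  expect_identical(fc$n[fc$criterion == "total"], nrow(x))
})

test_that("sample metadata TSV round-trips", {
  sim <- smallSim(seed = 45L)
  meta <- sampleMeta(sim$calls)
  path <- tempfile(fileext = ".tsv")
  writeSampleMeta(meta, path)
  back <- readSampleMeta(path)
  expect_identical(back$sample_id, meta$sample_id)
  expect_identical(back$birth_year, meta$birth_year)
  expect_identical(back$founder, meta$founder)
})
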