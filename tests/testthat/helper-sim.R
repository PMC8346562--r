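# Small simulation settings shared across test files: 12 samples on a
# three-chromosome 0.9 Mb genome with one planted duplication region.
smallParams <- function(seed = 11L, ...) {
  simParams(
    nSamples = 12L,
    chromLengths = c(ECA1 = 4e5, ECA2 = 3e5, ECAX = 2e5),
    nRefPrivate = 8L,
    dupRegions = data.frame(chrom = "ECA1", start = 50001, end = 90000,
                            multiplier = 4),
    seed = seed, ...)
}

smallSim <- function(seed = 11L, ...) simulatePopulation(smallParams(seed, ...))

# Minimal constructor wrapper for hand-built genotype fixtures.
makeCalls <- function(gt, chrom = "ECA1", pos = seq_len(nrow(gt)) * 100,
                      ref = "A", alt = "G", depth = NULL, ploidy = 2L,
                      chromLengths = NULL, ...) {
  SnvExperiment(chrom = rep_len(chrom, nrow(gt)), pos = pos,
                ref = rep_len(ref, nrow(gt)), alt = rep_len(alt, nrow(gt)),
                gt = gt, depth = depth, ploidy = ploidy,
                chromLengths = chromLengths, ...)
}
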