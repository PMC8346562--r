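---
title: "Methods: population SNV call-set characterization in PopSNV"
author: "PopSNV maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population SNV call-set characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PopSNV)
```

# The analysis model

PopSNV characterizes a multi-sample call set of biallelic SNVs from a
diploid population panel. Throughout, a panel of N individuals contributes
2N sampled alleles per site; a site is summarized by its ALT-allele count
`ac` (sum of per-sample dosages over called genotypes) and allele number
`an` (2 × called genotypes). Three population-genetic signatures organise
the analyses:

* **Singletons** (`ac = 1`): variants observed on a single sampled allele.
  They are the freshest class of variation, and their per-sample counts
  are informative about breeding structure — an individual whose genome
  has been widely inherited (a popular sire) shows *fewer* singletons than
  its contemporaries because its once-private variants have spread.
* **Reference-private candidates** (`ac = an`, no missing calls): the
  whole panel is ALT-homozygous, which is far more plausibly a unique
  allele in the reference individual than fixation of a new allele in the
  panel.
* **Collapsed-duplication pseudo-SNVs**: when two near-identical genomic
  copies are collapsed onto a single reference locus, every individual
  appears heterozygous for the paralogous difference, giving exact
  MAF 0.5, and the locus attracts both copies' reads, giving roughly
  doubled depth.

All analyses assume diploid autosomal-style genotypes everywhere,
including the X chromosome: the call sets this package targets genotype
all samples diploid on X, and no hemizygous handling is attempted. The X
is, however, excluded from the default singleton denominator (below).

# Hard filters

`applyFilters()` re-implements the classic GATK VariantFiltration hard
filters for SNVs; every expression *describes failure* and contributes an
additive FILTER label:

| label | expression | metric |
|---|---|---|
| lowDP | DP < 10 | site INFO depth |
| lowQUAL | QUAL < 50 | site quality column |
| lowQD | QD < 1.5 | quality by depth |
| highSB | SB > −0.1 | strand bias |
| highMQ0 | MQ0 ≥ 4 **and** MQ0/DP > 0.1 | mapping-quality-zero reads |
| snpCluster | ≥ 3 SNVs spanning ≤ 10 bp | local SNV density |

Numerical conventions: all comparisons are strict as written, so a site
sitting exactly on a threshold (QUAL = 50, QD = 1.5, SB = −0.1, DP = 10)
passes. The MQ0 test is a single conjunctive criterion, matching the
canonical hard-filter recipe it transcribes. The cluster rule follows the
upstream tool's ClusteredSnps convention: among a chromosome's sorted
positions, any run of `clusterSize` consecutive sites with
`last − first ≤ window` flags all its members; the window parameter is in
bp and both parameters are exposed. A criterion whose metric is absent
from the VCF is not applied, and this is logged once per run. Because
labels are recomputed from the metrics, filtering is idempotent, and
`passSites()` never reorders sites.

# Substitution spectrum and density

A substitution and its reverse complement are the same mutational event,
so the 12 ordered REF>ALT pairs collapse to 6 strand-symmetric classes;
the 4-way rollup merges the two transition classes and the two A:C-type
transversions, keeping A↔T and G↔C separate. `meanSpacing()` is total
surveyed bp divided by SNV count, rounded half-up.

Functional classes are assigned by precedence
(exon > 5′-UTR > 3′-UTR > intron > upstream > downstream > intergenic), so
a site in one gene's exon that also lies in a neighbour's flank counts
once, as exon. Density is reported as count × 1000 / *chromosome* length
(sites per chromosome-kb). The whole-chromosome denominator is the
convention such variant-database tabulations use — it makes intergenic
density highest simply because most of a chromosome is intergenic — and
because the alternative is also defensible, an optional
per-feature-bp density column (count × 1000 / annotated bp of that class)
is available via `densityTable(..., perFeature = TRUE)`.

Rounding conventions follow printed-table precision everywhere: allele
frequencies half-up at 4 decimals (`altFreq()`), singleton percentages at
1 decimal, all-heterozygous percentages at 2 decimals. Half-up rounding
(`roundHalfUp()`) is deliberate; base R's round-half-to-even would turn
1/202 into 0.0049.

# Site frequency spectrum and rare variants

`sfsTable()` is the histogram of `ac` over k = 1..2N, also reported in
REF-allele orientation (2N − k) for plotting. Sites with missing
genotypes contribute at their observed `ac` with a correspondingly
reduced `an`; a site is a singleton iff `ac = 1` regardless of `an`. The
panels this package targets are PCR-free high-coverage call sets with
essentially no missingness, so this is an extension choice rather than a
modelled behaviour.

The singleton *fraction* is reported with an autosomal denominator by
default (`autosomesOnly = TRUE`, chromosome names ending in "X"
excluded): the X is called in the same diploid panel but tabulated
separately in the summaries this mirrors, and mixing the two denominators
changes the headline percentage. `rareByGroup()` takes plain arithmetic
means of per-sample singleton counts within metadata groups (birth year
by default), ordered ascending.

# Collapsed-duplication detection

`dupScan()` composes three steps:

1. `maf05AllHetSites()` — candidates are sites with `ac = an/2` *exactly*
   and no missing genotypes; the all-heterozygous subset (every dosage 1)
   is the duplication signature proper. Exact equality rather than a MAF
   tolerance band matches the exact-count framing of the summaries this
   reproduces; the two conditions are kept separate because MAF 0.5 also
   arises from balanced homozygote mixtures.
2. `clusterCandidates()` — single-linkage merge of all-het candidates at
   gap ≤ `maxGap` (default 10 kb), keeping intervals with ≥ `minSites`
   (default 5). Sub-threshold micro-clusters — the dispersed
   several-hundred-bp pattern typical of small collapsed repeats — are
   reported separately rather than silently dropped.
3. `depthRatioTest()` — mean per-sample depth across all matrix sites in
   the interval versus the *median* depth of flanking sites within
   `flankBp` (default 50 kb); the median resists the occasional deep
   flank site. Verdict `duplication` at ratio ≥ `minRatio` (default 1.6).
   With no flank sites the chromosome-wide median substitutes and the
   call is `ambiguous-flank`.

The 1.6 default deserves a note: a clean 2× duplication does not yield a
measured ratio of 2.0, because the called interval also contains ordinary
segregating sites at baseline depth. With pseudo-SNVs entering at about
twice the background site rate, the expected interval mean is
(2·2x + 1·x)/3 ≈ 1.67x, so the threshold is set below that dilution point
but well above background fluctuation. Thresholds are all arguments.
Detected sites are flagged and reported, never removed from the call set
— with genotype data alone one cannot prove duplication, only assemble
converging evidence.

# Mitochondrial founder-line concordance

Mitochondrial genotypes are haploid (one allele per sample); diploid-coded
records are accepted only if every call is homozygous, and heterozygous
calls raise an error naming the sample and site. `founderConsensus()`
takes the per-site majority within each recorded founder group, breaking
exact ties toward REF and flagging them — consensus rather than a medoid
because it is robust to a single aberrant sample per group, which is
precisely the sample the discrepancy scan must then catch.

`flagDiscrepancies()` computes each sample's Hamming distance to its own
line's consensus: 0 is `consistent`; 1..`maxPrivate` (default 2) is
`mutation_drift`, the private mutations expected over roughly 30
generations of a closed studbook. For `lineage_discrepancy` — the
registration-error verdict — distance > `maxPrivate` alone is *not*
sufficient: the haplotype must also be strictly closer to another founder
line's consensus. The reason is quantitative: private-mutation counts are
open-ended (a Poisson(0.3) process puts a ≥3-mutation sample in roughly a
third of 101-sample cohorts), so a pure distance cutoff would regularly
misname drift as a pedigree error; a genuinely misregistered sample, by
contrast, sits tens of sites from its recorded line and within a mutation
or two of the line it actually belongs to. The nearest line and its
distance are reported alongside the verdict. With a single founder line no
discrepancy can be called.

# The synthetic population generator

`simulatePopulation()` exists so that every stage above can be tested by
exact recovery. Its defaults emulate a 101-horse Thoroughbred
resequencing panel:

| parameter | default | meaning |
|---|---|---|
| nSamples | 101 | diploid samples (2N = 202 alleles) |
| snvRate | 1/198 | segregating sites per bp |
| sfs shape | ∝ 1/i | neutral allele-count weights over i = 1..2N−1 |
| singletonBoost | 1 | multiplier on the i = 1 class |
| tsTvRatio | 2.0 | transition:transversion weight |
| coverageMean | 20 | per-sample Poisson depth |
| nRefPrivate | 30 | all-ALT-homozygous sites (scaled from ~3.5k per 12.2M) |
| dupRegions | ECA29:1–200,000, ×2 | planted pericentromeric collapse |
| failFraction | 0.05 | per-criterion hard-filter failure rate |

The default genome is 20 Mb over five chromosomes (ECA1–3, ECA29, ECAX) —
a deliberate desk-scale stand-in for a 2.41 Gb genome chosen so that
default runs produce ~1e5 sites; the analyses are linear in sites and
nothing in them depends on chromosome count. The panel's birth-year
distribution reproduces the emulated cohort exactly at n = 101 (19 birth
years from 1985 to 2016, heavily weighted to 2013–2016) and samples those
weights at other sizes.

Key design decisions:

* **Exact haplotype assignment.** Each segregating site draws its ALT
  count k from the normalized spectrum weights, then places exactly k ALT
  alleles on the 2N haplotypes by uniform permutation. The realized SFS
  therefore equals the drawn multiset *exactly*, making SFS recovery a
  sharp identity test instead of a statistical one. Singleton carriers
  are recorded in the truth ledger at draw time.
* **Deterministic substreams.** One master seed spawns an independent
  deterministic stream per chromosome (plus streams for sample metadata,
  coding impacts, and the mitochondrial genome), each derived only from
  the master seed and the stream name. Fixed seed ⇒ byte-identical VCF
  and ledger, and a chromosome's segregating positions do not change when
  other chromosomes are dropped from the configuration. Reference-private
  sites are apportioned across chromosomes by largest remainder
  (deterministic), so their total is exact.
* **Filter metrics are site-level draws.** QUAL/DP/QD/MQ0/SB are drawn
  per site so that each criterion fails independently with probability
  `failFraction`: pass and fail values are drawn from disjoint ranges
  with a margin around every threshold, and are rounded to 2 decimals at
  generation time so VCF round-trips are bit-exact. INFO DP is drawn
  rather than summed from the FORMAT depths — the two serve different
  purposes here (filter exercising vs duplication depth signal), and
  coupling them would make the per-criterion failure rate depend on the
  coverage model.
* **Depth model.** Per-sample per-site depth is Poisson(coverageMean),
  and Poisson(2 × coverageMean) at planted duplication sites — the
  simplest model exhibiting the doubled-coverage signature. Planted
  pseudo-SNV positions enter at `snvRate × multiplier` inside each
  region.
* **Mitochondria.** A fixed 16,660 bp genome; founder haplotypes are
  random binary vectors over the variable positions (pairwise distinct,
  ~50% divergence), each sample inherits its founder's haplotype plus
  Poisson(λ = 0.3) private mutations, and a fraction `errorRate` of
  samples silently receives another founder's haplotype while keeping its
  recorded label — the injected pedigree errors, listed in the ledger.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: linkage disequilibrium and
recombination structure (sites are independent), indels and multiallelic
records (skipped at input with a logged count), base-context mutation
biases beyond the Ts:Tv ratio, genotyping error and missingness,
population structure or relatedness among samples (the SFS shape is drawn
i.i.d. per site), and read-level artifacts other than the planted
depth/heterozygosity signature. The neutral 1/i default is a stand-in
shape, not an estimate of any real cohort's spectrum: selective breeding
skews real spectra, so simulated headline percentages (e.g. the singleton
fraction near 1/H(201) ≈ 17%) are internally consistent but not
comparable to a real panel's values.

# Problem sizes and verification

The test suite validates each operation against independent brute-force
oracles (interval scans, transitive-closure clustering, per-site filter
re-evaluation) on small fixtures, and runs exact-recovery checks on
simulated cohorts: unit tests use 8–30 samples on sub-Mb genomes, and the
end-to-end acceptance checks use the full default conditions — 101
samples, ~1e5 sites, coverage 20 — where the SFS, singleton carriers,
reference-private sites, the planted duplication region (Jaccard ≥ 0.95,
zero false calls) and injected mito errors are all recovered exactly, and
two pipeline runs produce byte-identical report bundles. These sizes were
chosen as the smallest at which every class of planted signal is
abundantly represented.

# Known limitations

* Genotype dosages only; the package never inspects reads, so duplication
  verdicts are evidence summaries, not proofs, and mapping-quality-driven
  exclusions can only be consumed (via INFO MQ0), not recomputed.
* Diploid-X convention: no hemizygous male handling; X-linked `an` values
  assume 2N alleles.
* The mito discrepancy scan requires ≥ 2 founder lines present in the
  cohort and assumes founder lines are well separated relative to
  `maxPrivate`; closely related maternal lines would compress the margin
  between drift and discrepancy.
* Coding impacts (`ann_impact`) are consumed from upstream annotation (or
  planted by the simulator), never recomputed from codons.
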