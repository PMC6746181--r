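---
title: "Single-molecule ctDNA detection: models and methods"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(plasmatrace)
```

plasmatrace implements a patient-specific circulating tumor DNA (ctDNA)
workflow end to end: selection of assay targets from multiregion tumor
sequencing, single-molecule resequencing of those targets in plasma with
UMI-based error suppression, spike-in calibration of molecule counts,
depth-downsampling re-analysis, and an orthogonal ultra-low-pass
whole-genome (ULP-WGS) copy-number readout of tumor content. A synthetic
data generator with complete ground truth drives every stage, so the whole
pipeline is testable without any sequencing data. This vignette records
the models behind each stage, the tunable parameters and their defaults,
and the design decisions taken where the method was genuinely open.

## The read-level simulator

Each target locus is an independent random contig carrying one somatic SNV
with at least 70 bp of flank, so a short amplicon (&le; 139 bp, the size
compatible with ~165 bp cfDNA fragments) can always be designed around the
variant. A library receives, per locus, `background_wt_molecules` wild-type
templates (default 1000 — roughly the genome equivalents recoverable from a
3 mL plasma aliquot) plus the spiked mutant templates. The generative model
per molecule is:

1. capture with probability `capture_efficiency` (default 0.5; losses
   during extraction and library prep are real but unquantified, so a
   round number near half);
2. a UMI drawn uniformly from the `4^umi_length` tags (default 7 bases,
   capacity 16,384);
3. library-prep errors applied once per molecule at `prep_error_rate` per
   base (default 1e-4). These are first-cycle errors: every read of the
   family inherits them, which is precisely the error class that survives
   consensus and that the caller's two-family detection rule exists to
   reject;
4. a geometric number of reads with mean `mean_reads_per_molecule`
   (default 12), mimicking PCR jackpotting, with the library total capped
   at `reads_per_library` (default 1e5) by hypergeometric thinning —
   a fixed sequencer allocation shared by all molecules;
5. per-read fragment lengths from N(165, 10) bp truncated to the amplicon
   and to cover the target base, and sequencing errors applied
   independently at `seq_error_rate` per base (default 1e-3), UMI bases
   included.

Reads are single-ended, carry the UMI inline as their first bases, and
repeat it in the read name after the last colon. What the generator does
*not* emulate: real genome sequence content and mappability, germline
variation, indels and structural variants, paired-end reads, and
base-quality structure. Tests passing on this generator therefore show the
*analysis logic* is correct under the stated error model, not that the
assay would perform identically on real libraries.

The benchmark design mirrors a two-source spike-in experiment: two
genotype sources, six log-spaced amounts (10^1..10^6 molecules) in
duplicate, four negative controls, two library preparations per sample —
24 spike-in samples and 56 libraries. The designed spike level of a
library is conserved exactly: it is split evenly across the loci
(remainder to the first loci), so per-library truth totals equal the
level.

## The UMI consensus caller

The caller reconstructs template molecules from raw reads in four steps.

*UMI extraction and locus assignment.* The first `umi_length` bases are
split off; reads shorter than `umi_length + 20` are discarded and tallied.
Assignment is alignment-free: each amplicon contributes an anchor 15-mer
(its 5' end), and a read belongs to the unique anchor matching its start
with at most one mismatch. Amplicons are short, synthetic and designed
with unique anchors, so full alignment buys nothing here; the chance of a
random 15-mer matching within one mismatch is below 1e-4.

*Family grouping.* Reads are grouped by exact UMI, then directionally
merged: tags within Hamming distance `umi_merge_distance` (default 1) are
joined whenever the larger count `b` and smaller count `a` satisfy
`b >= 2a - 1`. Families are the connected components of this rule —
without merging, sequencing errors inside the UMI masquerade as extra
molecules. The rule has a known cost at high tag occupancy: when a locus
holds thousands of families, most tags have an occupied Hamming-1
neighbour and merging collapses genuinely distinct molecules. That is the
mechanism by which the simulated assay saturates far below the 16,384-tag
capacity, and it motivates the calibration stage below.

*Consensus and filters.* The family's consensus base at the target
position is the majority vote (ties are ambiguous and never mutant). A
family votes mutant only if its consensus equals the expected alternate
allele, it holds at least `min_reads = 2` reads, and at least
`min_agreement = 0.9` of its reads agree. Single sequencing errors die in
consensus; singleton families (which could be lone errors) are excluded.

*Detection.* A locus is called detected when at least
`min_mutant_families = 2` independent families are mutant. Library-prep
errors convert whole families, but independently per molecule, so they
produce isolated mutant families at rate ~`prep_error_rate / 3` per
wild-type molecule; requiring two independent UMIs drives the per-locus
false-positive probability to ~1e-4 at the default background. Wild-type
families are counted and otherwise ignored. On the default simulation,
locus-level sensitivity at &ge; 10 mutant templates is ~95% and
specificity is 100% — the regime the assay is designed for.

## Spike-in calibration

Observed unique mutant families rise monotonically with input molecules
but flatten well below tag capacity (background occupancy, capture losses,
merge collapse). The calibration curve makes this quantitative without a
parametric model: support points are the per-level means of log10 observed
mutant families (replicates observing zero families are excluded; a level
with no observations at all is dropped with a warning), made non-decreasing
by isotonic regression, and interpolated piecewise-linearly in log-log
space. The inverse maps an observed count back to an estimated input
— zero maps to zero, observations below the calibrated range extrapolate
from the first segment and are flagged, and observations at or above the
plateau are clamped to the largest calibrated input and flagged, because
beyond saturation the count carries no quantitative information.

The collision model `expected_distinct(n, U) = U (1 - (1 - 1/U)^n)` gives
the ideal (error-free, merge-free) expectation and is verified against a
Monte-Carlo oracle in the tests. Back-calculated library totals recover
simulated inputs within a factor of two across the quantifiable range when
averaged over replicates; individual observations at 2–3 molecules are
dominated by capture Poisson noise and zero counts, which is why the
package reports and tests replicate-level recovery.

## Downsampling

`downsample_reads()` and `downsample_per_target()` sample uniformly
without replacement — downsampling models discarding reads before any UMI
processing, so it is applied to raw reads. `detection_vs_depth()` re-runs
the entire caller per depth and reports both the deduplicated-count
retention (which falls smoothly with depth, because families need
`min_reads` survivors) and binary detection (which is far more robust:
high-burden loci stay detected down to 10,000 reads per target).
Count retention and binary detection are deliberately separated: a ~50%
count reduction and unchanged detection can coexist, and the two answer
different questions.

## ULP-WGS copy number and tumor content

Bin counts (1 Mb default) are normalised by the median count of their GC
decile and expressed as log2 ratios against the autosome-wide median;
deciles with zero median coverage are masked. A bin with tumor copy number
`c` at tumor fraction `f` has expected depth ratio `(2(1-f) + c f)/2`, so
a single-copy loss at f = 0.30 sits at log2(0.85) = −0.234.

Segmentation is transparent recursive binary splitting: the candidate
split maximises the Welch t statistic and is accepted while the mean
difference is at least `penalty` (default 0.05 log2) with at least
`min_bins = 8` bins per segment. At the default simulated noise (~5%
count CV per bin, the Poisson floor at ~0.3x coverage plus moderate
overdispersion), segment means are then ~4 standard errors away from the
±0.1 state cuts, so zero-tumor genomes come out all-neutral in ≥ 19/20
runs. States are called by thresholding (`loss_cut = -0.1`,
`gain_cut = +0.1`).

Recurrent artifacts are removed cohort-wise: contiguous non-neutral
segments of each sample are merged into alteration intervals, and an
interval recurring (≥ 50% reciprocal overlap) in at least 80% of the
samples of the same collection batch is an artifact — tumor events are
private to a patient, collection-tube artifacts are shared. The merge step
matters because segmentation sometimes splits one shifted span into
adjacent segments that individually fail reciprocal overlap.

Percent tumor content inverts the single-copy model per qualifying
(altered, non-artifact, autosomal) segment — `f = 2(1 - 2^r)` for losses,
`f = 2(2^r - 1)` for gains — and averages bin-weighted, clipped to [0, 1].
With no qualifying segment PTC is *indeterminate*, not zero: an all-neutral
profile says the tumor fraction is below the detection floor, and the
package preserves that distinction (`NA` + `ptc_indeterminate`). PGA is
the altered fraction of analysed bins; reported ploidy is uncorrected
(twice the bin-weighted mean depth ratio). Multi-copy amplifications and
subclonal events violate the single-copy assumption and bias PTC upward
or downward respectively; the bundled prostate-like profile uses
single-copy events, where the inversion is exact.

One threshold interaction is worth stating plainly: a single-copy event at
f = 0.07 shifts log2 by only 0.0514, inside the default ±0.1 cuts, so the
defaults cannot see it — they are deliberately conservative for
artifact-robust screening. Low-fraction analyses (f ≤ ~0.10) use an
explicit sensitivity setting (`penalty = 0.03`, cuts ±0.04), chosen from
the closed-form shift, under which f ∈ {0.07, 0.14, 0.30} is recovered
within ±0.05 in the tests.

## Multiregion clonality and target selection

Mutation presence across tumor foci is binary. A mutation in all foci is
truncal, in exactly one focus a leaf, otherwise a branch. The clone tree
is the unique perfect phylogeny when the matrix is conflict-free (no pair
of mutations exhibits all three of the 11/10/01 focus patterns); otherwise
columns are dropped greedily — most conflicts first, ties to the smaller
focus count — until conflict-freeness is restored, and the dropped
mutations are reported rather than silently placed. Assay targets are
ranked trunk first, then branches by descending focus count (prevalence
proxies clone size), leaves excluded by default, ties broken by genomic
coordinate so selection is deterministic. Amplicon design around selected
targets enforces the ≤ 139 bp bound, ≥ 20 bp flanks where the locus
permits, unique anchor 15-mers, and shifts windows whose anchor contains a
homopolymer run of 8+. Thermodynamics (melting temperature, dimers) are
not modelled; anchor uniqueness and the homopolymer rule stand in for
designability.

The generator draws a random (or caterpillar/balanced) clone tree,
assigns mutations to edges with at least one truncal mutation, and emits
the implied matrix — so classification and tree reconstruction can be
verified exactly against truth, which the test suite does across 50
random instances.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on simulated data at
sizes chosen to exercise every code path with tight statistical checks:
spike-in benchmarks of 5–8 loci per panel and levels 10^1–10^4 over ten
seeds (~4 × 10^5 reads per seed), ULP-WGS genomes of 2,875 one-megabase
bins with recovery grids of ten seeds per tumor fraction, and multiregion
instances of up to 7 foci and 25 mutations. Determinism is enforced
end to end: every stochastic function takes a seed, identical seeds give
byte-identical FASTQ output, and the directional-merge and segmentation
algorithms are themselves deterministic (ties broken lexicographically or
by genomic order).

Known limitations, beyond the generator's scope notes above: the caller
handles SNVs only (no indels, no phasing, no duplex consensus); molecule
quantification is uninformative at and above curve saturation by
construction; the copy-number stage is a transparent estimator, not a
probabilistic tumor-fraction model, and reports uncorrected ploidy; and
clone trees are built from point mutations only, since only point
mutations are resequenced in plasma.
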