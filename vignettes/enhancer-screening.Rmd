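---
title: "Screening multi-region H3K27ac ChIP-seq for tissue-specific enhancers"
author: "edgescreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening multi-region H3K27ac ChIP-seq for tissue-specific enhancers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edgescreen)
```

# The screening problem

Enhancers are distal cis-regulatory DNA elements that restrict when and where
a promoter fires. Because a short enhancer fragment fits comfortably inside a
recombinant adeno-associated virus (rAAV), an enhancer with genuinely
tissue-restricted activity can be paired with a minimal promoter to build a
viral tool that expresses a transgene only in the cell population the
enhancer serves — the enhancer-driven gene expression (EDGE) strategy.

The screen starts from H3K27ac ChIP-seq, the standard chromatin mark of
active enhancers, assayed across many micro-dissected brain regions with
replicates. The computational question is: *which putative enhancers are
active in exactly one tissue group?* `edgescreen` implements that screen as a
chain of small, separately testable stages, plus the in-silico cloning and
quality-control arithmetic needed to carry a candidate from coordinates to a
titered rAAV construct, and the histology statistics used to evaluate the
resulting tool.

# Pipeline model, stage by stage

## Unified atlas

Per-sample peak calls (BED) are merged into a unified atlas with
`merge_peaks()`: intervals overlapping by at least 1 bp fuse; *bookended*
intervals (touching end-to-start) stay separate. The union-of-overlaps
reading keeps every base that any sample called enriched while never joining
two adjacent but distinct regulatory elements that happen to abut. Atlas ids
are `"<chrom>:<start>-<end>"` in the same 0-based half-open coordinates the
BED files use. Merging runs across all samples at once rather than within
tissue groups first; with overlap-merging the two orders give the same atlas,
and a single pass avoids an arbitrary grouping decision.

## Signal quantification and normalization

`quantify_signal()` sums binned coverage over each atlas interval, weighting
each bin by the fraction of it the interval overlaps, so partitioning an
interval conserves signal mass exactly. `normalize_signal()` applies
counts-per-million scaling per sample followed by `log2(x + 1)`. Neither step
is prescribed by the screening idea itself; CPM removes library-size
differences between samples and the log stabilizes the variance that the
downstream Pearson correlations and z-scores assume. The pseudocount of 1 on
the CPM scale keeps empty intervals at exactly zero.

## Sample concordance

`correlation_matrix()` computes Pearson correlations between samples over all
atlas rows of the normalized signal. Atlas rows (rather than fixed genome
bins) dominate the genome-wide variance of an enrichment assay and are
available without re-reading coverage; for H3K27ac concordance Pearson on
log-CPM is the common choice. `hierarchical_cluster()` then runs
average-linkage (UPGMA) agglomeration on the distance `d = 1 - r`, with
samples pre-sorted by label so tie-breaks are deterministic.
`replicate_cohesion()` reports the fraction of samples whose nearest
neighbor (highest off-diagonal correlation) belongs to the same tissue —
the quantitative version of "replicates cluster together". Tissues with a
single sample cannot contribute and are listed as excluded.

## Cross-tissue z-scores and the ceiling at sqrt(T - 1)

`tissue_means()` averages replicate columns per tissue group;
`zscore_matrix()` standardizes each atlas row across the `T` tissue means
with the population SD:

    z_t = (x_t - mean(x)) / sd_pop(x)

Constant rows are set to zero and flagged rather than producing NaNs.
Z-scoring across tissue means (not raw samples) matches the screen's
question — tissue-level uniqueness — and averages out replicate noise;
a sample-level matrix is available by passing the identity sample sheet.

One algebraic fact governs every threshold on these scores: for a row of
`T` values, the largest possible z is `sqrt(T - 1)`, attained only when the
remaining `T - 1` values are exactly equal. A perfectly one-hot enhancer
(active in 1 of `T` tissues, identical background elsewhere) sits *exactly*
at that bound when `T = 5`, because `sqrt(T - 1) = 2`. Any noise pushes the
score strictly below it. Consequences:

* With many tissue groups (say 19 regions, ceiling ~ 4.24) the conventional
  "2 SD" cutoff is a meaningful interior threshold.
* With the 5 tissue groups of the default synthetic dataset, `z_min = 2.0`
  coincides with the ceiling and admits nothing. The screen's operating
  threshold must be read against `T`; at `T = 5` the package's own analyses
  use `z_min = 1.5`, comfortably above the noise of shared enhancers
  (whose scores concentrate near 0) and below the one-hot ideal of 2.

`unique_enhancers()` keeps `z_min` at the conventional default of 2.0 and
exposes it; the end-to-end examples in this package state explicitly which
value they use.

## K-means assignment

`kmeans_assign()` clusters z-score rows with Lloyd's algorithm from k-means++
seedings (10 restarts, best within-cluster sum of squares kept, fixed seed).
The default `k` is `T + 1`: one cluster per tissue plus one to absorb
broadly active enhancers. Each cluster is labeled with the tissue of its
largest centroid coordinate, or `"unassigned"` when no coordinate reaches
`z_label_min = 0.5`. Note that because every non-constant row is standardized
to unit variance, "flat" rows do not shrink toward zero — they become
unit-variance noise and may join the cluster of whichever tissue their noise
points at. On well-separated data this does not disturb the tissue clusters
(assignment accuracy of planted enhancers is checked in the tests), but the
label of a broadly active enhancer should not be over-interpreted.

## The uniqueness gate

`unique_enhancers()` combines two filters, mirroring the two published
screening steps — a z-score cut for "significantly unique" signal and an
intersection against peak calls from other tissues:

1. `z(target) >= z_min`;
2. the interval overlaps peak calls in at most `max_ref_hits` samples from
   non-target tissues (default 0: any reference-tissue peak disqualifies).

Either gate can be disabled. Results are ordered by descending target z.
Lowering `z_min` is monotone (result sets nest), which the tests assert.

## Candidate selection

Four annotations rank the screened candidates for cloning:

* **Repeat fraction** (`repeat_fraction()`): overlap with the repeat BED or,
  equivalently, the soft-masked (lowercase) genome fraction; when both
  sources are given they must agree exactly. Threshold: at most 0.2 masked.
* **Conservation** (`conservation_score()`): base-weighted mean of a [0,1]
  track; uncovered bases count 0 and the covered fraction is reported.
  Threshold: at least 0.5.
* **Nearest gene** (`nearest_gene()`): distance from the enhancer midpoint to
  the nearest strand-aware TSS (`start` for `+`, `end` for `-`), ties to the
  smaller coordinate. The midpoint is symmetric and stable under small
  boundary changes, unlike an edge-based distance. The gene id is emitted for
  a manual expression-pattern lookup; no expression filter is applied.
* **Target z** carried through from the screen.

The published criteria are qualitative ("low degree of repeats", "high
conservation"), so the numeric thresholds above are this package's choices,
exposed in `selection_thresholds()`. `rank_candidates()` sorts all passing
candidates ahead of failing ones, then by descending z, ascending repeat
fraction, descending conservation, and id — a deterministic total order.

## In-silico cloning

`design_primers()` reproduces the published primer layout exactly: a 6-nt
tail (`GTGTAC`), the restriction site (EcoRI `GAATTC` forward, SalI `GTCGAC`
reverse), and a genomic anchor — 22 nt of the enhancer 5' end for the
forward primer, the reverse complement of the final 26 nt for the reverse.
Those anchor lengths are the ones implied by the published 34/38-nt primers
for the vHC-20-72 enhancer; no melting-temperature optimization is applied.
`in_silico_pcr()` requires both anchors to match the template exactly once
(ambiguity and absence are distinct errors) and returns the template plus the
24 flanking bases. `assemble_construct()` models the sticky-end digestion
(both enzymes cut after their first base: `G^AATTC`, `G^TCGAC`) and ligation
into a backbone whose polylinker sits upstream of a 134-bp minimal promoter
and reporter. Both junction sites reconstitute, so re-digestion releases the
amplicon interior exactly — the round trip back to the enhancer sequence is
lossless and is asserted for seeded random enhancers in the tests. The
backbone shipped by `make_backbone()` is synthetic: the real plasmid sequence
is not published, so only its layout and the 134-bp promoter length are
modeled, and the promoter feature is explicitly named
`minimal_promoter_synthetic`.

## qPCR titration

`fit_standard_curve()` fits `Cq = slope * log10(copies) + intercept` to a
serial dilution of linearized plasmid (convention: five 10-fold dilutions,
1e9 down to 1e5 copies) and derives the amplification efficiency
`10^(-1/slope) - 1`; a slope of `-1/log10(2) = -3.3219` is a perfect
doubling, efficiency 1. `qpcr_titer()` inverts the curve at a sample's Cq and
scales by the dilution factor and reactions-per-ml factor. Extrapolation
outside the curve's Cq range triggers a warning, and titers outside the
plausible rAAV window of 1e11-1e14 genome copies/ml are flagged (typical
preparations run 1e12-1e13).

## Co-expression statistics

`coexpression_stats()` computes the two percentages behind histology pie
charts from cell-count tables: the share of reporter-positive (eGFP+) cells
that are marker-positive, and the share of marker-positive cells that are
reporter-positive. The default pools counts across rows before dividing,
matching the single-number style of published pie charts; per-animal and
per-section modes report group means with SD, since pooling and averaging
genuinely differ when section sizes vary. Wilson 95% intervals accompany the
pooled estimates — the score interval stays inside [0,100] and behaves at
extreme proportions (99.95%-style counts), where the Wald interval fails.
Zero denominators yield a flagged "undefined", never a silent 0.

# The synthetic data generator

`simulate_dataset()` builds the whole study in miniature with known ground
truth:

* **Genome**: 2 chromosomes x 1 Mb of uniform random sequence (sizes are the
  package's choice of a desk-scale problem; every stage is linear in genome
  size).
* **Repeats**: contiguous runs soft-masked as lowercase, covering 10% of the
  genome, with the repeat BED exactly matching the lowercase runs.
* **Enhancers**: 200 shared (active in all tissues), 50 tissue-specific per
  tissue, and 5 decoys per tissue planted *inside* repeat runs so the repeat
  filter has true signal to remove. All enhancers are 500 bp, bin-aligned,
  non-overlapping, and at least one enhancer length apart (placement on a
  fixed slot grid guarantees this by construction).
* **Coverage**: per 100-bp bin, negative-binomial counts with
  `variance = mu + 0.1 * mu^2`, background mean 5, and mean 40 (fold 8)
  inside enhancers active in the sample's tissue; 5 tissue groups x 2
  replicates, each sample seeded independently from the master seed and its
  id. NB is the standard overdispersed count model for ChIP-seq coverage and
  keeps recovery nontrivial; dispersion 0 selects the Poisson limit.
* **Conservation**: per-bin Beta(1,4) background (mean 0.2) lifted to
  Beta(8,2) (mean 0.8) over conserved enhancers — a usable separation for
  testing the filter, with no claim of realism.
* **Toy peak caller**: a bin qualifies at `min_fold = 4` times the
  genome-wide median bin count; adjacent qualifying bins merge; runs shorter
  than `min_width_bp = 200` (two bins) are dropped. At the default contrast
  this recovers over 99% of active enhancers per sample with a negligible
  background rate (the probability of one background bin reaching the
  threshold is about 1e-4, and two consecutive are required). This caller is
  deliberately a stand-in: the published pipeline's peak caller and its
  settings are not restated here, and no attempt is made to mimic a
  MACS-class model.

What the generator does *not* emulate: read-level artifacts
(fragment-length, GC bias, mappability), input/control tracks, biological
covariance between enhancers, or realistic repeat/conservation structure.
Passing tests therefore demonstrate that the *algorithms* are correct and
that the chain recovers planted truth under a fair noise model — not that
any particular real dataset would yield a particular atlas.

# Numerical choices and degenerate inputs

* Population (not sample) SD in z-scores; constant rows flagged, all-zero.
* Zero library size, zero-variance samples, unknown tissues/ids, malformed
  BED records, non-uniform bin widths: all hard errors naming the offender.
* Chromosomes absent from a coverage track contribute zero signal with a
  warning (a legitimate situation for sparse toy tracks).
* K-means: empty clusters or indistinct centers exhaust 10 restarts, then one
  re-seed, then error. Fixed seeds make every clustering reproducible.
* Relative activity uses `(tissue mean + 0.5) / (grand mean + 0.5)`; the 0.5
  pseudo-signal keeps ratios finite for silent enhancers on the log-CPM
  scale. The cross-tissue grand mean serves as the reference signal.
* Correlation matrices are symmetrized after asserting the raw asymmetry is
  below 1e-10, and the diagonal is set to exactly 1.
* UCSC-style coordinate strings are 1-based inclusive and converted to
  0-based half-open on parsing.

# Problem sizes and runtime

The default dataset (2 Mb, 20,000 bins x 10 samples, 475 planted enhancers)
simulates in a few seconds and the full screen completes in about ten; the
whole test suite, including 10 re-simulations for the clustering stability
check, runs in about two minutes on one CPU. These sizes were chosen so that
properties are measured with enough planted instances (at least 250
tissue-specific enhancers) to make the 90% recovery bounds statistically
stable.

# Known limitations

* The screen consumes peak calls; it does not call peaks on real data.
* The conservation and repeat models are caricatures adequate for testing
  filter logic only.
* The uniqueness gate counts any overlapping reference peak, regardless of
  its strength; a weighted variant would need the reference coverage, not
  just calls.
* The backbone is a synthetic stand-in; real construct QC must swap in the
  actual plasmid sequence.
* With few tissue groups the z ceiling compresses the score scale (see
  above); thresholds tuned on many-region atlases do not transfer to small
  panels unchanged.
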