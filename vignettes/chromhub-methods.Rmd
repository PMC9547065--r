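---
title: "Models and methods behind chromhub"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chromhub}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`chromhub` integrates binned Hi-C topology (contact matrices, loops, TADs,
A/B compartments) with regulatory annotation (chromatin states,
super-enhancers), expression, eQTLs and GWAS variants. This vignette
documents the models, the parameters that matter, the numerical choices,
what the synthetic-data generator does and does not emulate, and the known
limitations. It states no empirical result that the package's tests and
acceptance script do not themselves compute.

## Coordinate conventions and the interval engine

All internal coordinates are 0-based, half-open (`[start, end)`, the BED
convention). Two intervals overlap iff they share a chromosome and
`a.start < b.end && b.start < a.end`. Variant tables — conventionally
1-based — are converted at the reader boundary and converted back on
output, so a single convention holds everywhere in memory.

The interval engine (overlap join, closest feature, windowed signal sums)
is written so that its output is *defined* to equal a brute-force
all-pairs scan; the engine prunes candidates by a binary search over
subject starts, and the test suite asserts exact equality with literal
double-loop oracles on thousands of randomized cases, plus an independent
cross-check against `IRanges::findOverlaps`. `closest_feature()` breaks
distance ties deterministically (smaller feature start, then input order);
`bedtools closest` reports all ties, so an `all_ties` flag exposes the
same behaviour. Variants are treated as 1-bp points throughout; loop feet
are the caller's fixed-width bins (5 kb here), and "variant on a loop
foot" means the point lies within the foot interval.

Loop *size* is the distance between foot midpoints: the quantity is
invariant under foot-order permutation and insensitive to foot width,
which matters because loop-size distributions are compared across
conditions.

## Contact-matrix layer

**Expected by distance.** For each separation `d` (in bins), the mean
over valid pixels at that separation. Separations whose pixels are all
masked are `NA`, never zero — downstream observed/expected ratios must
not silently divide by an imputed value.

**Compartments.** The canonical principal-component method: the
observed/expected matrix over valid bins, its Pearson correlation matrix,
and the leading eigenvector. The sign of an eigenvector is arbitrary, so
it is oriented against an external reference track (gene density or an
active mark such as H3K27Ac): bins with above-median reference signal must
average positive, positive bins are labelled `A`. The compartment
resolution defaults to 100 kb (the matrix is sum-aggregated first); the
sliding-window variant used by some callers is not reproducibly specified,
so non-overlapping bins are used instead — a documented divergence.
Degenerate inputs (uniform matrices, rank-0 correlation) raise an error
rather than emitting an arbitrary single-label call. The call is invariant
under uniform scaling of the matrix because both the expected values and
the correlation are scale-free.

**Diamond insulation.** For bin `i` and window `w = window_bp/bin_size`,
the raw score is the *mean* of valid pixels in the off-diagonal diamond
`{i−w..i−1} × {i+1..i+w}` — contacts crossing bin `i` — and the reported
value is `log2(raw / chromosome-wide mean raw)`. This is the convention in
which boundary insulation is measured from contacts crossing the boundary
region itself, not normalized by adjacent-region contacts; the
normalization choice matters because adjacent regions rich in local loops
(SE neighbourhoods) would otherwise bias boundary scores. A constant
matrix scores exactly 0 everywhere valid; the first and last `w` bins are
invalid. Per-TAD boundary insulation averages the scores of the two bins
containing the TAD's start and end coordinates (a single containing bin
per boundary; whether a window around the boundary should be used instead
is not specified anywhere authoritative, and the single-bin choice is the
most local one).

## CREs and super-enhancer calling

Chromatin-state segments carrying active labels (one promoter state plus
five enhancer states in the default ten-state vocabulary) are merged at
gap 0 into CREs. Before stitching, CREs *fully contained* in a promoter
window (TSS ± 2.5 kb — the same half-width used for promoter eQTLs) are
removed; partial overlaps are kept, since removing them would delete
distal enhancers that merely brush a promoter window. Stitching chains
CREs whose gap is below 12,500 bp, the ROSE default, kept configurable
because SE calls are sensitive to it.

Case and input H3K27Ac coverage are summed over constituent CREs only
(stitched gaps excluded — the ROSE convention) and the net signal is
`max(case − input, 0)`, with the subtraction done constituent-wise. The
elbow is formalized discretely: with regions ranked ascending and both
axes min-max scaled, the cutoff index is `argmin(y − x)`, the point where
a convex rank curve has tangent slope 1. Ties take the *largest* index —
the conservative direction, fewer SEs. Regions strictly above the cutoff
signal are SEs. Degenerate inputs (all-equal signals, or the exactly
linear curve where `y = x` everywhere) yield zero SEs with a warning. The
whole construction is invariant under affine rescaling of the signal.

## Resampling nulls and the df = 99 enrichment t

Two nulls mirror the two standard tools:

- *Random regions* (`bedtools random` semantics): fixed length (the median
  SE length), fixed count (the SE count), chromosome chosen proportional
  to placeable length, start uniform; regions may overlap one another.
- *Random TADs* (`regioneR` semantics): the observed TAD length multiset
  is permuted and placed without overlap, so each set preserves the count
  and the mean length exactly. Placement assigns lengths to chromosomes at
  random subject to capacity and distributes the slack by uniform
  stick-breaking, which succeeds deterministically whenever the total
  fits; this is why the generator keeps planted TADs at ~75% genome
  coverage.

The enrichment statistic is the one-sample t of the `n = 100` random
values against the observed value treated as a constant:
`t = (mean(random) − observed) / (sd(random)/√n)`, df = n − 1 = 99,
two-sided p. Negative t means the observed value exceeds the random mean.
An empirical-quantile p is also reported but is not the default.

One property of this design deserves emphasis: the t treats the observed
value as *fixed*. Its size is exact under the null "the random-value
population mean equals the observed constant", and that is how the
package's calibration test is run (rejection at α = 0.05 within 5% ± 2%
over 2,000 simulations). If instead the observed value is itself a draw
from the same distribution as the random values, its sampling noise is
not in the denominator and the test rejects far above nominal — by
roughly √n-fold inflation of |t|. Consequently a single shuffled-variant
realization is *not* statistically indistinguishable from the random-TAD
null under this t, even when unbiased; the shuffle control is therefore
validated by checking that its same-TAD share falls within the null
spread (random-set mean ± combined placement-plus-binomial SD), not by
the t itself. With 100 planted-enrichment comparisons (e.g. the ~70%
same-TAD share against ~50% null shares) the t is enormous and the design
works as intended.

## eQTL classification

Each record is one variant–eGene pair; all counts are at pair level. The
promoter/distal boundary is ±2.5 kb of the eGene TSS, *inclusive* at
exactly 2,500 bp. Trans pairs (different chromosomes) are annotated distal
with a flag and excluded from TAD co-residence. The pieQTL taxonomy
collects every loop with a foot covering the variant and inspects the
opposite feet against promoter windows of *all* genes: any eGene-promoter
hit ⇒ `egene_pieqtl`; else any promoter hit ⇒ `non_egene_pieqtl`; else
`eqtl_only`; no foot ⇒ `not_on_loop`. A variant on several loops takes
the highest class — one record per pair, best-supported mechanism.
Regulatory overlap gives SE precedence over CRE, and "region overlaps the
eGene" uses the gene body (a TSS-only mode exists). H3K27Ac context sums
coverage in the inclusive ±100 bp window around the variant and compares
distal versus promoter strata with Welch's t (Satterthwaite df; distal
listed first, so promoter-high signal gives negative t).

## GWAS variant-to-gene linking

LD variants are filtered inclusively at MAF ≥ 1% and r² ≥ 0.7 (LD tables
are inputs; LD computation against a reference panel is out of scope).
Loop targets: any loop with one foot on the variant links the opposite
foot's gene-body overlaps (`loop_to_body`) and TSS hits (`loop_to_tss`),
one link per (variant, gene, mechanism, loop). Shared-element targets
link a variant to every gene whose body or TSS overlaps the same CRE/SE
that contains the variant. The nearest-gene fallback uses the closest
gene body with the engine's deterministic tie-breaks. Summaries
deduplicate variants per category, and `check_links()` re-verifies each
link's cited evidence against its mechanism predicate. A second loop set
(another tissue) can be supplied for side-by-side counts.

## The synthetic genome

`simulate_bundle()` emits everything the pipeline consumes, with truth
labels. The defaults are the study conditions under which the package's
acceptance checks run; they were chosen once, on scale arguments, and are
not tuned against test outcomes.

- **Genome**: two 10 Mb chromosomes; 5 kb matrix bins; 100 bp signal
  bins. This is the smallest scale at which 100 kb insulation windows,
  ~800 kb TADs and 5 kb loop feet coexist comfortably, and it keeps a
  full run in minutes on one CPU (the methods' problem sizes, not a
  statement about any particular machine).
- **TADs**: lengths drawn from 500 kb–1.1 Mb (multiples of 100 kb, mean
  800 kb), in contiguous runs of 3–5 TADs sharing boundaries, separated
  by 0.8–1 Mb unorganized gaps (~75% coverage). Shared boundaries are the
  planted insulation boundaries: the diamond score has a well-defined
  minimum there, whereas a TAD edge facing an unorganized gap sits on a
  depleted plateau with no localizable minimum, so run edges are recorded
  as TAD edges but not as insulation-boundary truth. The sub-100%
  coverage is also what makes non-overlapping random-TAD placement
  feasible.
- **Compartments**: each TAD gets an A/B label in runs of 1–2; label
  blocks extend through half of each flanking gap, so segments tile the
  chromosome, every TAD is fully contained in one segment, and all
  breakpoints are 100 kb-aligned. Contact enrichment ×1.5 for same-label
  bin pairs, ×3 for same-TAD pairs, ×4 at planted loop anchors, on a
  `(d+1)^(−1)` distance-decay expectation with base level 50 at the
  diagonal, then Poisson-sampled (negative binomial available for
  overdispersion robustness checks).
- **Super-enhancers**: 20 SEs, each four 1.5 kb constituents separated by
  7 kb gaps (27 kb span, within the reported order of magnitude for SE
  domains), planted only in A TADs; 20% at TAD edges (2 kb from the
  boundary, the "edge SE < 5 kb" class), the rest ≥ 20 kb inside.
  Constituent H3K27Ac rate 20/bp versus background 1/bp (the default
  contrast), typical enhancers 2–8/bp, promoter states 12/bp, input 1/bp,
  all Poisson-noised per 100 bp bin. SEs are placed before genes, and
  genes are laid out around them — regulatory geometry constrains gene
  placement rather than the reverse, which also makes placement
  deterministic-feasible at any seed.
- **Genes**: ~290 regular genes (5–15 kb, ~65 kb spacing, random strand)
  plus two short genes hosted in each SE's internal gaps, positioned so
  their promoter windows never swallow SE constituents. Expression is
  log-normal (meanlog 2, sdlog 0.4 — a deliberately compact spread so
  group means are stable at n ≈ tens); B-compartment genes are attenuated
  ×0.3 and carry no promoter state (silent chromatin), and SE-hosted
  genes are boosted ×2.0 — the planted fold the recovery check targets.
- **eQTLs**: 25 variants per planted loop class (eGene pieQTL, non-eGene
  pieQTL, eQTL-only, not-on-loop), 25 promoter eQTLs, 15 SE-overlapping,
  15 CRE-overlapping, 10 promoter-CRE variants (the promoter stratum of
  the H3K27Ac comparison). eGenes are drawn uniformly from the gene table
  so variant shuffling is unbiased with respect to TAD coverage; the
  freely placeable classes are then planted to bring the overall
  variant–eGene same-TAD share to the 70% target. A bin registry
  guarantees class purity: a planted not-on-loop variant's bin can never
  later acquire a loop foot.
- **GWAS**: two diseases × four loci — two loop loci (lead + three
  filtered LD variants on a foot facing a gene body, one of them also a
  TSS), one shared-element locus (an SE-resident lead for one disease, an
  intronic-CRE lead for the other), and one loop-free control locus whose
  variants are guaranteed off every loop foot and element, giving the
  no-spurious-links check teeth. LD blocks carry 20 variants with uniform
  r² and MAF so the inclusive filter is exercised on both sides of both
  bounds.

What the generator does *not* emulate: read-level noise, mappability and
balancing artifacts, overlapping genes and alternative TSS, LD structure
beyond a block label, trans contacts, and hg38 scale. Passing recovery
tests therefore demonstrate the *correctness of the classification and
calling logic under clean planted geometry*, not robustness to the full
noise spectrum of real Hi-C and ChIP data. The Poisson count noise and
signal-track noise do exercise the numerical paths (elbow stability,
insulation minima localization, compartment eigenvectors at ×1.5
contrast).

## Numerical choices and degenerate inputs

- Empty inputs return empty results; interval joins never error on them.
- Zero-variance random values: the enrichment t is undefined; direction
  is still reported, with a warning.
- All-masked diagonals: expected values are `NA`, never 0.
- Insulation bins with no valid diamond pixel are flagged invalid; TADs
  with both boundary bins invalid are flagged rather than dropped.
- `rose_cutoff` with fewer than three distinct signal values: zero SEs,
  warning.
- Welch strata with fewer than two records per group are skipped with a
  warning rather than returning a meaningless statistic.
- Determinism: every stochastic component takes a mandatory seed;
  `simulate_bundle()` derives independent sub-seeds per component so
  toggling one component leaves the others byte-identical.

## Known limitations

- Matrix balancing (KR/ICE) is accepted as input but not implemented; raw
  synthetic matrices are used in the tests.
- Loop calling and TAD calling are out of scope: their outputs are inputs
  here, and the generator emits planted loops/TADs directly.
- The compartment caller assumes cis-only, single-chromosome matrices;
  trans-based compartment refinement is not attempted.
- The conservation metric assumes a strict 1:1 ortholog map and
  gene-body loop overlap; paralog families must be resolved upstream.
- Per-locus GWAS summaries deduplicate variants by rsid within disease;
  variants shared between loci through overlapping LD blocks count once.
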