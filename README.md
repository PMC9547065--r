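# chromhub

Integrative analysis of 3D genome topology with regulatory elements and
disease variants, in tidyverse-style R.

Deeply sequenced Hi-C maps of a tissue — such as the adult human retina —
yield chromatin loops, topologically associating domains (TADs), A/B
compartments and insulation profiles. Interpreting them requires
integration with regulatory annotation (chromatin states, H3K27Ac-defined
super-enhancers), expression, eQTLs and GWAS variants. `chromhub`
implements that integration layer as a set of composable, tibble-in /
tibble-out functions:

- **Genomic core** — a coordinate-validated interval engine (overlap
  joins, closest-feature with deterministic tie-breaks, windowed signal
  sums) whose every operation is contractually identical to a brute-force
  all-pairs scan, plus readers/writers for BED, BEDPE, bedGraph, gene /
  variant TSV and plain-text contact matrices. All internal coordinates
  are 0-based half-open; 1-based variant tables are converted at the
  reader boundary.
- **Matrix topology** — expected-contact-by-distance, A/B compartment
  calls (leading eigenvector of the Pearson correlation of the
  observed/expected matrix, sign oriented by an active-chromatin reference
  track), the diamond insulation score
  `log2(mean diamond contacts / chromosome mean)` with 100 kb windows, and
  per-TAD boundary insulation.
- **Super-enhancer calling** — merge active chromatin states into CREs,
  drop TSS-contained CREs, stitch within 12.5 kb (the ROSE default), score
  case-minus-input H3K27Ac over constituents, and place the rank-curve
  elbow at `argmin(y - x)` on the min-max-scaled curve, the discrete
  slope-1 tangent point.
- **Resampling nulls** — 100 sets of random SE-sized regions (length =
  median SE length, count = SE count, overlaps allowed) and 100 sets of
  non-overlapping random TADs preserving the observed length multiset;
  enrichment is the one-sample t of the 100 random values against the
  observed statistic, `t = (mean(random) − observed)/(sd(random)/√n)`,
  df = 99, so negative t means enrichment.
- **SE topology** — edge (< 5 kb from a TAD boundary) versus central SE
  placement, TAD classification by compartment and hosted-SE position,
  per-TAD and per-region loop statistics, boundary-crossing fractions,
  expression folds, and a cross-species gene-pair conservation metric
  (shared-TAD and loop-connected fractions under a 1:1 ortholog map).
- **eQTL integration** — promoter (±2.5 kb of the eGene TSS, inclusive)
  versus distal classes, compartment assignment, variant–eGene TAD
  co-residence versus random TADs, the pieQTL loop taxonomy (eGene pieQTL
  / non-eGene pieQTL / eQTL-only / not-on-loop), CRE/SE overlap with SE
  precedence, and Welch t-tests on ±100 bp H3K27Ac context.
- **GWAS linking** — inclusive MAF ≥ 1% and r² ≥ 0.7 LD filtering, then
  variant-to-target-gene links via loop feet (`loop_to_body`,
  `loop_to_tss`), shared CREs/SEs, and nearest-gene fallback, with
  deduplicated per-locus summaries.
- **Synthetic data** — `simulate_bundle()` generates a fully seeded toy
  genome (two 10 Mb chromosomes, 5 kb matrix bins) with planted TADs,
  compartments, loops, SEs, expression boosts, eQTL classes and GWAS loci,
  plus machine-readable truth labels, so the whole pipeline is testable
  end to end without any download.

Results follow tidyverse conventions: `tidy()`/`glance()` methods for
fitted objects (`se_call`, `enrichment_result`, `compartment_call`,
`conservation_summary`) and `autoplot()` methods for the SE rank curve,
insulation tracks and enrichment histograms.

## Worked example

```r
library(chromhub)
library(dplyr)

# a synthetic retina-like bundle with planted truth
bundle <- simulate_bundle(synthetic_config(), seed = 1)

# CREs -> TSS exclusion -> stitching -> signal -> elbow
cres <- merge_active_states(bundle$states)
proms <- promoter_regions(bundle$genes, 2500, bundle$build)
stitched <- exclude_tss_cres(cres, proms) |>
  stitch(12500) |>
  region_signal(bundle$case_track, bundle$control_track)
call <- rose_cutoff(stitched)
glance(call)
#> # A tibble: 1 x 4
#>   n_regions  n_se cutoff_index cutoff_signal
#>       <int> <int>        <int>         <dbl>
#> 1       101    20           81        15387.

# insulation and compartments from the contact matrix
ins <- diamond_insulation(bundle$matrices$chr1, window_bp = 1e5)
cc <- compartment_call(bundle$matrices$chr1, bundle$case_track)
glance(cc)
#> # A tibble: 1 x 5
#>   chrom n_bins   n_A   n_B n_segments
#>   <chr>  <int> <int> <int>      <int>
#> 1 chr1     100    57    43          7

# variant-eGene TAD co-residence against 100 random TAD sets
rt <- sample_random_tads(bundle$build, bundle$tads, n_sets = 100, seed = 42)
st <- same_tad_analysis(bundle$eqtls, bundle$tads, bundle$genes, rt)
st$enrichment
#> <enrichment: same_tad_proportion observed=0.6975 random=0.4923+/-0.0301
#>              t(99)=-68.135 p=5.42e-85 [observed_higher]>
```

The elbow call flags 20 of 101 stitched regions as super-enhancers (all
20 planted SEs, no false calls); 69.8% of the planted variant–eGene pairs
share a TAD, versus 49.2% ± 3.0% across the 100 random TAD sets — a df=99
enrichment of t = −68.1 (negative t = observed above the null, the
convention used throughout).

A single driver runs every stage and returns a serializable run report:

```r
report <- run_pipeline(bundle, seed = 1)
write_report(report, "report.json")
```

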