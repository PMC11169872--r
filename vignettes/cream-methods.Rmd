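---
title: "CREAM methods: simulation model, pipeline decisions and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CREAM methods: simulation model, pipeline decisions and statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cream)
```

This vignette documents the scientific model behind the package, the
parameter defaults, and the design decisions taken where the underlying
laboratory protocol leaves room for interpretation. It is the methods
reference; the README covers usage.

## 1. The comparative digestion model

Each sample is digested twice with the anchor enzymes NsiI (`ATGCAT`, cut
offset 5) and PstI (`CTGCAG`, offset 5) plus one member of the MspI/HpaII
isoschizomer pair at `CCGG` (offset 1). MspI ignores CpG methylation;
HpaII is blocked at a methylated internal CpG. Only fragments with exactly
one anchor-derived end and one `CCGG`-derived end are ligated into the
library (a barcoded adapter fits the anchor overhang, a common adapter the
`CCGG` overhang), and only fragments of 200–400 bp (inclusive) survive
size selection.

A cut is modelled as the single top-strand coordinate
`motif start + cut offset`; sticky-end overhangs are ignored for length
bookkeeping, a ≤ 4 bp effect that cancels between libraries. All
coordinates are 0-based half-open.

Comparing the MspI and HpaII fragments that share an anchor cut gives the
per-sample status: **A** (identical — unmethylated), **B** (MspI only),
**C** (both present, shared anchor end, HpaII longer), **D** (HpaII only).
B/C/D all imply a methylated `CCGG`. Status C carries a directional
assumption: the two fragments must agree on the anchor-side coordinate and
differ on the `CCGG` side, because methylation can only move the `CCGG`
end (the anchor cut is methylation-insensitive). Pairs of intervals that
differ at both ends are therefore classified `ambiguous`, never C.

On i.i.d. uniform DNA a 6-bp site recurs every $4^6 = 4096$ bp; two
distinct 6-bp anchors combine by summing cut rates,
$(1/4096 + 1/4096)^{-1} = 2048$ bp (`combined_anchor_spacing()`). The
`CCGG` site recurs every $4^4 = 256$ bp. These closed forms are exposed
and tested against observed spacings on long random sequences.

## 2. The simulator

`simulate_experiment()` generates, per seed, a complete experiment:
genome, per-sample methylomes, ground truth and paired-end alignments.

**Genome.** `n_chrom = 2` chromosomes of `chrom_length = 5e6` bp, i.i.d.
bases at `background_gc = 0.33`, with 30-kb genic blocks at
`genic_gc = 0.50` covering `genic_block_fraction = 0.30` of each
chromosome (greedy non-overlapping placement of uniform draws). The GC
contrast is the lever for the gene–methylation density correlation: `CCGG`
is 100 % GC, so `CCGG` density — and with it the density of capturable,
methylatable loci — rises in genic blocks. Problem sizes (10 Mb, 20
samples, depth 30) are the package's own choice of a desk-scale experiment
that a laptop pipeline run completes in about a minute.

**Methylome.** Each `CCGG` site receives a layered state per sample:

- base layer: methylated with `base_methylation_prob = 0.40`;
- line layer: each clonal line flips the base state with
  `line_epimutation_rate = 0.05`;
- sample layer: each sample flips its line state with
  `sample_epimutation_rate = 0.01`.

State = `base XOR line_flip XOR sample_flip`. The layers directly generate
the three spectrum classes of a clonal population — shared (k = n),
line-exclusive (k = line size) and singleton (k = 1) loci — with
closed-form class probabilities used by the acceptance tests, e.g.
$P(\text{monomorphic}) = [p_b(1-p_l)^2 + (1-p_b)p_l^2](1-p_s)^n$.
The rates were chosen once, before any pipeline run, to give a spectrum
with all three peaks clearly populated (~72 % of loci methylated); they
are the study conditions, not tuned values.

**Reads.** Every size-selected fragment is sequenced
`Poisson(depth = 30)` times as a proper pair: read 1 covers the fragment
start forward, read 2 the fragment end reverse-complemented, both
`min(read_length = 150, fragment length)` bp, MAPQ 60, SAM flags 99/147.
`substitution_error_rate` (default 0) injects i.i.d. substitutions,
recorded in `NM` and applied to emitted sequences. Limits of realism: no
indels, no chimeras, no partial digestion, no adapter read-through, no
mapping ambiguity — the simulator validates the pipeline's logic, not an
aligner.

**Determinism.** Every stochastic stage seeds its own stream via a hash of
`(seed, stage tag)`, so per-seed outputs are byte-identical and inserting
a new stage does not reshuffle the others.

**Ground truth.** Truth regions are keyed by `(chrom, anchor_pos,
anchor_end)` — the anchor cut coordinate and which fragment end it is.
This key is invariant to methylation because MspI digestion is
sample-independent; the per-sample status is then derived from which
library's fragment passes size selection.

## 3. Pipeline decisions

- **Alignment filter**: primary, properly paired, MAPQ ≥ 20, NM ≤ 5, mate
  on the same chromosome. All thresholds boundary-inclusive.
- **Sample exclusion**: a sample is dropped when its raw read count
  averaged over the two libraries falls below
  `min_reads_per_library = 1e5` (inclusive). This is a real-data guard;
  toy simulations disable it with `min_reads_per_library = 0`.
- **Insert reconstruction**: a pair's insert is
  `[min(read starts), max(read ends))`; identical intervals within a
  (sample, library) collapse into a support count. An optional boundary
  check (`check_boundaries`) verifies one insert end abuts an anchor cut
  and the other a `CCGG` cut in the reference.
- **Locus calling**: one left-to-right sweep merges all inserts (any
  sample, any library) sharing ≥ 1 bp of overlap; abutting half-open
  intervals do not merge.
- **Coverage filter**: a locus is retained when ≥ `ceiling(0.5 × n)`
  samples have summed insert support ≥ `cov_min = 20` across both
  libraries. Reading choice: the support is summed over the two libraries
  of a sample (they sequence the same region of the same genome), and the
  half-of-samples rule uses the post-exclusion sample count.
- **Presence**: a library is "present" at a (locus, sample) when it has an
  insert with support ≥ `presence_min = 5`; below that, sparse support is
  treated as absence rather than evidence. With presence in both
  libraries, interval equality is judged within `end_slop` (default 0 —
  the simulator is exact; real data would use a small slop).
- **Ambiguity is reported, not dropped**: more than one distinct interval
  in a library, or intervals differing at both ends, yields `ambiguous`;
  loci where no sample is informative are summarised `ambiguous`, and
  masked cells are `NA` in the binary matrix.

## 4. Population statistics

- **Spectrum**: counts of loci by number of methylated samples k.
  Line-exclusive loci require all samples of one line methylated, none of
  the other line, and no masked cell in the line.
- **Subculture test**: Kruskal–Wallis on per-sample methylated-locus
  counts grouped by subculture number, via `stats::kruskal.test`
  (midranks, tie correction); the all-tied degenerate case returns
  H = 0, p = 1 rather than 0/0.
- **PCA**: on the binary methylated view (1 = B/C/D, 0 = A, NA masked),
  masked cells imputed with the locus mean, columns centered, not scaled.
  Encoding choice: statuses B, C and D are one biological state
  (methylated) observed through different fragment geometries, so they are
  not given separate codes.
- **Densities**: fixed 500-kb bins per chromosome, final partial bin
  included, features counted by start coordinate (a locus spans ≪ bin
  size, so the rule is immaterial at default scales but must be fixed for
  determinism). Correlation by Spearman's rho (`stats::cor`, midranks),
  `NA` with a warning for constant inputs.
- **Enrichment**: per-term one-sided hypergeometric test
  (`stats::phyper`) of target transcripts (near methylated loci) against
  the background universe of transcripts near any captured locus —
  transcripts, not the whole genome, because capture is already biased by
  `CCGG`/anchor density. BH adjustment across terms; flat term map, no
  ontology propagation.

## 5. Numerical and engineering choices

Established implementations are used for every standard step — Biostrings
motif matching (overlap-aware, `fixed = TRUE` so `N` never matches),
Rsamtools/GenomicAlignments for SAM/BAM, IRanges/GenomicRanges for
interval algebra, `stats` kernels for all tests — while the comparative
digestion logic, the layered methylome, the classification rules and the
spectrum are implemented here, each validated against independent naive
oracles in the test suite (enumerate-all-cuts digestion, transitive-closure
locus merging, explicit midrank statistics, `choose()`-sum hypergeometric
tails).

Integer coordinates are kept as R integers (well within 2^31 at all
supported scales); depth sums use doubles. Fragment tables, matrices and
statistics are plain tibbles or small S3 objects (`cream_methylotypes`,
`cream_spectrum`, `cream_pca`) with `tidy()`/`glance()`/`autoplot()`
methods.

## 6. A minimal run

```{r example, eval = FALSE}
cfg <- sim_config(n_chrom = 1, chrom_length = 1e6,
                  n_lines = 2, n_samples = 3, seed = 7)
sim <- simulate_experiment(cfg)
res <- call_methylotypes(sim$records, genome = sim$genome,
                         config = pipeline_config(min_reads_per_library = 0))
frequency_spectrum(res, sim$samples)
pca_methylotypes(res, sim$samples)
run_popstats(res, sim$samples, genes = sim$genes, genome = sim$genome)
```
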