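---
title: "chipsummit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chipsummit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What the package computes

`chipsummit` implements the downstream half of a multi-factor,
multi-replicate ChIP-seq study: everything after read mapping and peak
calling. The motivating setting is chromatin profiling of Polycomb
accessory proteins (the Arabidopsis VEL family — VIN3, VRN5, VEL1 —
profiled before and after prolonged cold), but every stage is generic:

1. **Significance filtering.** Peak callers are typically run
   permissively (e.g. MACS-style q = 0.05). Downstream analysis then
   retains only highly significant peaks, here those with
   Q-value ≤ 10⁻¹⁰, i.e. `-log10(Q) >= 10`, threshold inclusive. The
   filter is applied per replicate, *before* consensus construction,
   so that weak single-replicate calls can never seed a consensus
   region.
2. **Consensus peaks.** Replicate peak sets of one factor/condition
   are pooled and clustered by transitive overlap; a cluster becomes a
   consensus peak when its members span at least two distinct
   replicates.
3. **Gene assignment.** Each consensus peak is represented by its
   summit; a summit within 1 kb upstream of the TSS to 1 kb downstream
   of the TTS of a gene is assigned to that gene, the closest gene
   winning when several qualify, and peaks with no gene within 1 kb
   remaining unassigned. Distinct assigned genes per factor/condition
   give the target-gene table.
4. **Co-occupancy.** For factor pairs, the percentage of one factor's
   peaks overlapped (≥ 1 bp) by the other's; for more factors, the
   partition of a reference set by which other factors co-occupy each
   peak. Gene-level comparisons against external target lists
   (e.g. H3K27me3 or H2AK121ub domains) use exact set arithmetic with
   an optional hypergeometric enrichment test.
5. **Metagene profiles.** Replicate coverage tracks are summed, scaled
   to 1× genomic content (RPGC: genome-wide mean coverage exactly 1),
   and averaged over genes with bodies rescaled to a fixed number of
   bins plus fixed-width flanks. Input tracks are profiled identically
   and shown as controls, never subtracted.

## Coordinate conventions

Externally the package speaks the formats' native dialects: narrowPeak,
BED and bedGraph are 0-based half-open; GFF3 is 1-based inclusive.
Internally everything is a `GRanges`/`Seqinfo`/`RleList` in the
standard R/Bioconductor 1-based closed convention, converted exactly at
the I/O boundary. The observable semantics are those of the BED world:
adjacent intervals (`[a,b)` and `[b,c)`) do not overlap, but they *do*
merge when clustering (`min_gap = 0` means "touching or overlapping");
a gap of exactly `min_gap` base pairs does not merge.

Distances are coordinate differences, not gap sizes: the distance from
a summit to a gene is 0 inside the gene body and otherwise
`|summit − nearest end base|`. This is one larger than a "gap"
distance and matches the inclusive reading of "within 1 kb": a summit
exactly 1000 bp upstream of the TSS is still assigned.

## Decisions where the rules underdetermine the implementation

Several choices are genuinely open in the verbal description of this
kind of pipeline; `chipsummit` fixes them as follows and exposes the
knobs:

* **Consensus support** is cluster-based: a transitively overlapping
  cluster counts as "present in" every replicate that contributes at
  least one member peak; two peaks from the same replicate count once.
  A base-pair-level intersection rule would be stricter; the
  cluster rule is the simplest one consistent with counting one
  consensus peak per reproducible region. `min_support` is
  configurable down to 1 (with a warning) for single-replicate
  controls.
* **Consensus extent and summit**: the region is the union span of
  the cluster; the summit is taken from the member with the highest
  −log10 Q (ties: leftmost summit). Union keeps clusters maximal and
  monotone in `min_support`; the best-q summit is the member most
  confidently localized.
* **Closest gene** is measured summit→gene *body*, not summit→TSS:
  the candidate window is the body ± 1 kb, so body distance is the
  metric that generated the candidates. Ties break to the
  lexicographically smallest `gene_id`, making results independent of
  input order.
* **Metagene geometry** defaults to 1 kb flanks, 100 body bins and 20
  flank bins (50 bp each). None of these is canonical; all are
  arguments. Body bins assign base `i` of a length-`L` body to bin
  `floor(i * bins / L)`, i.e. near-equal base spans with the bin value
  the mean coverage of its span; genes shorter than `min_gene_length`
  (default: one base per body bin) are excluded. Flank bins that run
  off the chromosome are `NA` and are dropped from the averaged
  profile's per-bin `n`.
* **Effective genome size** for RPGC defaults to the total assembly
  length and is configurable, since mappability-corrected sizes are
  assembly- and pipeline-specific.
* **Run configuration** is YAML — the lingua franca of bioinformatics
  workflow configs in R — with relative paths resolved against the
  config file and a manifest (record counts, config checksum, package
  version) written next to the outputs. Outputs carry no timestamps,
  so a rerun on identical inputs is byte-identical.

## The simulator: what it emulates, and what it does not

`sim_config()`/`simulate_experiment()` generate a complete synthetic
experiment so that every stage can be validated against planted truth
without any sequencing data. The generator emulates the *statistical
structure* the pipeline relies on:

* multiple factors × two conditions × several replicates of peak
  sets, with per-factor site counts that differ strongly between
  factors and rise after the cold condition (defaults: VEL1 300/280,
  VIN3 30/150, VRN5 120/220 sites for NV/cold at desk scale, three
  replicates);
* inter-factor **sharing**: each site of the first (hub) factor is
  copied into every other factor with probability `sharing`
  (default 0.8, echoing the observed majority co-occupancy), with
  small positional jitter; the remaining quota is factor-specific;
* **reproducibility**: each replicate realizes each site
  independently with probability `reproducibility` (default 0.9), so
  consensus recovery has a closed-form binomial expectation
  P(X ≥ 2), X ~ Bin(R, r);
* **summit placement** as a three-way mixture: TSS-anchored (default
  0.6), anchored slightly downstream of the TTS (0.25, mean offset
  150 bp), or intergenic (0.15), with Gaussian jitter (σ = 200 bp);
  gene-anchored summits are clamped into the gene's assignment window
  so planted gene labels are recoverable by construction;
* a **Q-value mixture** in which a configurable fraction (default
  0.3) of realized peaks falls below the 10⁻¹⁰ filter;
* **coverage** as Gaussian bumps (amplitude 20, σ = 200 bp) on a
  uniform background (level 1), written as fixed-resolution bedGraph
  steps, with flat matched input tracks.

Determinism: each sub-generator seeds R's RNG from the configured seed
with a fixed offset (annotation: `seed`; peaks: `seed + 1`; coverage:
`seed + 2`) and draws in a documented loop order
(conditions → factors → sites → replicates), so a seed fixes every
output byte.

What the simulator does **not** model — and therefore what passing
tests do not establish about real data: read-level noise and mapping
artifacts, fragment-length effects, GC and chromatin-accessibility
bias, peak-width/intensity correlation, overlapping or nested gene
models, and any temporal dynamics of the cold response beyond
different site counts per condition. Recovery results on synthetic
data validate the *algebra* of the pipeline, not the biology of any
particular antibody.

## Numerical and degenerate-input choices

* Peak files with missing summit offsets (column 10 = −1) fall back to
  the interval midpoint (`floor((start0 + end0)/2)`), so plain BED
  input remains usable; files with missing Q-values are rejected by
  the filter rather than silently passed.
* Empty inputs are legal everywhere they can occur: an empty
  narrowPeak file is an empty peak set; an empty consensus set writes
  an empty BED; an empty set in an overlap matrix yields `NA` rows and
  columns (never 0%); a zero-peak sample contributes `(0, 0)` to the
  target table.
* An all-zero coverage track cannot be RPGC-scaled and is an error.
  Normalized tracks satisfy genome-wide mean 1 to better than 1e−9
  (validated against direct summation).
* Text serialization uses up to 15 significant digits via
  `as.character()`, which round-trips every value the simulator emits
  (values are rounded to ≤ 6 decimals at generation) and keeps files
  human-readable and byte-stable across runs.

## Validation scale

The shipped checks run the interval engine against quadratic
brute-force oracles (hundreds of randomized instances on 10 kb
two-chromosome toy genomes), binomial-recovery experiments with 500
planted sites on 2 × 25 Mb genomes, metagene numerics on 10–500 kb
genomes with 20–60 genes, and a committed 300 kb / 35-gene / 3-factor
× 2-condition fixture with golden pipeline outputs. These sizes were
chosen so the whole suite runs in about a minute while keeping Monte
Carlo standard errors small relative to the tested tolerances (all
stochastic checks use 3-standard-error bands).

## Known limitations

* Consensus support is cluster-based only; a reciprocal-overlap or
  bp-level intersection mode is not implemented.
* No IDR or other statistical reproducibility model — the two-of-R
  rule is a hard threshold.
* Gene models are flat spans: no transcript isoforms, UTRs or nested
  genes; for overlapping real-world annotations the closest-gene rule
  resolves ties deterministically but cannot recover ambiguity.
* bigWig and BAM are out of scope: coverage enters as bedGraph.
* The hypergeometric gene-set test assumes a well-defined finite
  universe supplied by the user; none is inferred.
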