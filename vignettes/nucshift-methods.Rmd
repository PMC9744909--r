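---
title: "Methods: differential promoter nucleosome occupancy with nucshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential promoter nucleosome occupancy with nucshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucshift)
```

## The measurement and its model

Paired-end MNase-seq reads out nucleosome protection: the enzyme digests
linker DNA, and the midpoint of each surviving ~150 bp template estimates a
nucleosome dyad. `nucshift` turns aligned read pairs into per-base-pair
occupancy tracks and scores, per gene, how much occupancy the promoter
nucleosome-depleted region (NDR) gains in a test condition relative to a
reference. The biological setting it is designed for is a conditional
depletion ("degron") experiment in which promoter NDRs fill with
nucleosomes at a subset of genes — for example cohesin-loader depletion
acting through the RSC remodeler — with rescue strains providing baseline
comparisons.

The per-gene coordinate system is anchored on the +1 nucleosome dyad, the
first well-positioned nucleosome of the gene body, supplied as a BED6
annotation. All windows are strand-oriented: negative offsets are upstream
of the +1 nucleosome on the gene's strand, which is the NDR side.

## Read-pair filtering

A pair is kept iff all five predicates hold, evaluated in this order:
concordant; both mates on one chromosome; not ambiguously mapped; insert
(template) size within `[min_insert, max_insert]` = [120, 200] bp, bounds
inclusive (the rule removes pairs *outside* the range, so 120 and 200
survive); and at most `max_mismatch` = 4 mismatches in *each* mate (the cap
applies per read, not to the sum). Removal is attributed to the first
failing predicate, which makes the per-class report deterministic under any
input ordering. The 120–200 bp range keeps mono-nucleosomal templates;
the mismatch cap removes poorly aligned pairs.

"Ambiguously mapped" is not uniquely defined by aligner output; the package
operationalizes it as mapping quality ≤ 0 on either mate when reading BAM
(`mapq_ambiguous`, configurable), or bit 2 of the flag word in the BEDPE
dialect. Malformed records (a concordant pair with `end <= start`) abort
with the record index rather than being silently dropped.

## Occupancy tracks

`build_track()` reconstructs a DANPOS-style smoothed, count-normalized
dyad-coverage track with four parameters, all exposed:

* `width` (40 bp): each fragment midpoint *m* is extended to the footprint
  window `[m − width/2, m + width/2)` — for the even default, 20 bp on the
  left and 19 bp on the right of the midpoint inclusive. Windows are
  truncated at chromosome ends; there is no wraparound or reflection.
* `target_count` (10,000,000): the raw track is multiplied by
  `target_count / n_fragments_used`, a linear library-size scaling to a
  common effective count so conditions are comparable. Consequently the
  sum of the unsmoothed track equals `width × target_count` exactly
  whenever no footprint window is truncated, a conservation property the
  tests assert.
* `smooth_width` (20 bp): a centred moving average; for the even default
  the window at position *i* is `[i − 10, i + 9]`. Edge windows are
  truncated to the available positions and divided by their actual length.
  `smooth_width = 1` disables smoothing.
* span is fixed at 1 bp.

The order of operations is extend → scale → smooth. Scaling and smoothing
commute, so only the placement of extension matters, and extension must
precede smoothing for the footprint to be smeared correctly. Midpoints use
`floor((start + end)/2)` on the 0-based half-open template interval; the
floor is the documented tie-break for odd template lengths. An empty
fragment set yields an all-zero track with a warning instead of a division
by zero. Linear (not quantile) count normalization was chosen because the
scaling constant is the only normalization the track parameters imply;
the choice is isolated behind `target_count` so alternatives can be tested.

Tracks serialize as run-length-encoded bedGraph (full-precision text) or
bigWig. bigWig stores 32-bit floats, so its round-trip guarantee is
relative (~1e-7), not absolute; the bedGraph round-trip is exact to 1e-6.

## Promoter window statistic and gene selection

For gene *g* with dyad *d* and strand *s*, the statistic is the mean of
`test − ref` occupancy over positions `d + s·j`, `j = −150..−50` inclusive
(101 values). The window bounds follow the NDR interval scored for
occupancy gain; genes whose window leaves the chromosome are excluded and
flagged, before ranking, per comparison.

* **Blacklist**: genes that do not achieve *more than* a +0.6 occupancy
  difference (statistic ≤ 0.6, strict inequality for survival) are removed
  from heatmaps; lists from several comparisons merge by set union. The
  aggregator is the same −150..−50 mean statistic — the only statistic the
  procedure defines — rather than, say, a maximum over the plotted region;
  the threshold and direction are arguments so other readings can be
  explored.
* **Ordering**: descending statistic, ties broken by gene id
  (lexicographic, stable, radix sort), so an ordering computed on one
  comparison is reproducible across platforms and can be applied to every
  other comparison's heatmap.
* **Top-N** (default 500): when a baseline comparison is declared (e.g. a
  rescue strain vs wild type), its per-gene statistic is subtracted before
  ranking, removing gains already present in the control.

Statistics stay on the linear occupancy scale; log₂ is used only for
display matrices, `log2((test + c)/(ref + c))` with pseudocount `c = 1`
normalized unit, because zero-occupancy positions exist. Heatmap and
profile flanks default to ±500 bp around the dyad; heatmap assembly is pure
row selection, never value-altering.

## The synthetic generator

`simulate_fragments()` emulates the statistical structure the analysis
assumes, at the level of aligned fragment coordinates only:

* per gene, `n_nucleosomes` = 5 phased dyad sources at
  `+1 + k × 165 bp` (strand-oriented), weight 1 each, with Gaussian
  midpoint jitter (`dyad_jitter_sd` = 20 bp, a typical phasing spread);
* one NDR source per gene, uniform midpoints over the strand-oriented
  `ndr_window` = −160..−20 bp, weight `ndr_baseline_weight` = 0.2 (a
  depleted region, a fifth of a nucleosome); in the perturbed condition,
  affected genes (a `round(fraction × n_genes)` subset drawn once from the
  config seed) gain `ndr_fill_effect` = 0.8, filling the NDR to 5× its
  baseline weight;
* a uniform genomic background at 10% of clean fragments, so tracks are
  nonzero between arrays;
* clean template lengths Normal(150, 15) truncated to [121, 199] by
  inverse-CDF sampling, so the 120/200 filter boundaries are probed only by
  deliberately injected contaminants and filter tests are exact;
* contaminant classes (discordant, inter-chromosomal, short < 120 bp,
  long > 200 bp, > 4 mismatches in one mate) each fail exactly one filter
  predicate, making ground-truth labels and per-class filter counts
  comparable record-for-record. Mismatches are carried as integer counts
  (the BAM edit-distance tag), not simulated at sequence level, because the
  filter consumes only the count.

Everything is deterministic given the config seed; per-sample draws use a
seed derived from it (or an explicit `sample_seed`, used for independent
replicate samples).

What the generator does *not* model: sequence composition (GC, positioning
motifs), MNase digestion bias, base qualities, fragment-length dependence
on position, a −1 nucleosome upstream of the NDR, and any transcriptional
coupling. Passing tests therefore demonstrate the correctness of the
pipeline's arithmetic and selection logic and its statistical behaviour
under idealized Poisson sampling — not robustness to the biases of real
MNase libraries.

## Problem sizes and statistical behaviour

The test suite runs a compact design (two 60 kb chromosomes, 40 genes,
8,000–20,000 fragments) for unit and property checks, and a recovery
experiment of 3,000 genes with 500 NDR-filled and 200,000 clean fragments
per sample for parameter-recovery and null-control checks; these sizes
keep any laptop run under a minute per file. At that depth an affected
gene's NDR emits ~11 fragments against ~2.5 for an unaffected gene, and
about 70% of a filled NDR's footprint (uniform over −160..−20) falls inside
the scored −150..−50 window. The resulting separation of the window
statistic is ≈3.4 standard deviations of the counting noise: the affected
and unaffected distributions separate decisively in direction (rank-sum
p ≪ 1e-6), while the top-500 precision the suite measures sits somewhat
below 0.9, which is the expected normal-tail behaviour at this sampling
depth rather than an implementation property. The null control (zero fill
effect) shows overlap with any fixed 500-gene set consistent with the
hypergeometric expectation, i.e. no systematic enrichment.

## Degenerate inputs and numerical choices

* Empty fragment sets, empty gene lists and all-blacklisted heatmaps
  return valid empty objects with warnings (or errors where the operation
  is undefined, e.g. an empty `gene_set` for a profile).
* Oracle comparisons in the tests use 1e-9 relative tolerance for the
  smoothing convolution and 1e-12 for window statistics and log2 matrices;
  filter and ordering oracles are exact.
* `n_genes × gene_footprint` is validated against the usable genome before
  simulation; violation is a sizing error naming the constraint.
* The pipeline driver writes every stage artifact (filter reports, tracks,
  statistic tables, blacklists, ordering, heatmap matrices, top-N lists,
  profiles) as TSV/text plus a JSON provenance record (package version,
  config, config hash, seed), and rerunning an identical config is
  byte-identical.

## Known limitations

Blacklisting by "more than +0.6 difference" removes, at face value, every
gene without a strong occupancy *gain* — on real genome-wide data that is
most genes; the package implements the rule literally with the threshold
and aggregator configurable, and leaves the interpretation to the user.
The +1-dyad annotation is consumed as given (typically from chemical
mapping data); no attempt is made to call +1 positions from the MNase data
itself. Alignment and adapter trimming are upstream of the package: it
consumes aligned records (BAM or the documented BEDPE dialect) and its
concordance/ambiguity semantics are only as good as the aligner's flags.
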