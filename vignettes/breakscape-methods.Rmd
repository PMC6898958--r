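---
title: "Detecting evolutionary breakpoint regions from synteny: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting evolutionary breakpoint regions from synteny: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breakscape)
library(dplyr)
```

## The problem

When two chromosome-level genomes are compared, most of their sequence
falls into long stretches of conserved gene order — homologous synteny
blocks (HSBs). The places where conserved order breaks down are
evolutionary breakpoint regions (EBRs): the intervals on one genome
between two adjacent HSBs, bounded exactly by the HSB end coordinates on
each side. When the two flanking blocks map to *different* chromosomes of
the partner genome, the EBR marks an interchromosomal event — in
karyotypes that differ mainly by chromosome number, a fission. EBRs are
interesting in their own right: across mammals they are repeatedly
reported to be gene-dense, GC-rich, repeat-rich (LINE-L1 in particular)
and enriched for specific gene functions.

breakscape implements this comparison chain end to end — anchors, HSB
chaining, EBR detection, fission counting, cross-comparison EBR unions,
feature and gene-set enrichment — together with a karyotype rearrangement
simulator that plants known breakpoints, so every stage can be validated
against ground truth. A separate module reconstructs chromosome-level
layouts from flow-sorted-library coverage and reference synteny, the way
chromosome-level assemblies of non-model species are actually put
together.

All coordinates inside the package are 0-based, half-open. BED files keep
that convention on disk; GFF3 and AGP are converted at the I/O boundary.
Tables are tibbles throughout and chain with the pipe.

## The simulator defines the study conditions

`simulate_ancestor()` draws chromosome lengths from a gamma model
(`length_mean`, `length_cv`), places non-overlapping gene models at
`gene_rate` per Mb (Poisson starts by default; `"regular"` placement gives
a fixed anchor spacing when tests need one), and covers each chromosome
with non-overlapping repeat intervals per family to the fractions in
`repeat_mix`. Sequences are i.i.d. nucleotides at a background GC chosen
so that, with repeat text generated at `gc_target + repeat_gc_shift`
(default +0.12), the *genome-wide* GC lands on `gc_target` (default 0.42,
a typical mammalian value). There are no indels, no nucleotide-level
evolution, no segmental duplications: the model is deliberately the
simplest one that gives the three feature statistics (gene density, GC,
repeat coverage) realistic structure.

`apply_rearrangements()` represents each derived chromosome as an ordered
list of ancestor segments with strand. Fission, fusion, inversion and
translocation rewrite the segment list; total length is conserved exactly
and, by default, cut positions avoid gene bodies (set
`avoid_genes = FALSE` to allow gene-disrupting breaks, which then drop the
clipped gene copies). Every cut is recorded as a 2-bp ground-truth
interval *in the ancestor coordinate frame*: that is the frame in which
EBRs are detected when the derived genome is aligned back to its
ancestor-like partner, and ancestor coordinates never move under later
events, so truth recorded once stays valid. `breakpoint_bias` multiplies
the sampling weight of candidate positions inside repeat intervals
(default 1 = uniform); `flank_enrichment` plants extra genes or
family-specific repeats around the chosen breakpoints until the local
density reaches a chosen multiple of the genome-wide density — this is how
the tests create a known repeat/gene/GC signal for the enrichment
statistics to recover.

`emit_anchors()` turns the surviving ortholog map into anchors with
configurable dropout (Bernoulli per pair), coordinate jitter (Gaussian,
clamped to the chromosome) and micro-inversions (orientation flips only).

Defaults used by the bundled pipeline (`default_config()`) are desk-scale:
a handful of chromosomes of a few Mb, ~12 genes/Mb, LINE-L1/SINE/LTR
repeat mix totalling 27%. They emulate the statistical structure of a
mammalian comparison, not its size; nothing in the method depends on
genome scale beyond run time.

## Anchors

`find_exact_matches()` reports every maximal exact match of length at
least `min_len` (default 20) between two sequences, via shared k-mer
seeding (k = `min_len`) and per-diagonal run scanning; `N` never matches
anything. The test suite checks it against a brute-force quadratic oracle
on sequences up to 200 bp, including reverse-strand coordinates.
`anchors_from_orthologs()` makes one anchor per ortholog pair (orientation
= product of the two strands, weight = smaller gene span);
`cluster_matches_to_anchors()` merges raw matches onto ortholog pairs
within a `window` (default 10 kb — the clustering radius of the original
tooling is not published, so this is exposed rather than claimed).

## Chaining anchors into HSBs

Within each (chromosome A, chromosome B, orientation) stratum,
`chain_anchors()` finds score-maximal chains by weighted
longest-increasing-subsequence dynamic programming: anchor *j* may precede
*i* iff both genomes advance strictly in the chain direction and the gap
on each genome is at most `max_gap` (default 2 Mb; negative gaps, i.e.
overlapping anchors, are allowed). Chains are extracted greedily — best
chain first, its anchors removed, repeat — so each anchor belongs to at
most one block; ties go to the longer span on genome A, then input order.
The optimality of the extracted chain scores is verified against
exhaustive subset enumeration on 500 random instances in the test suite.

"Large-scale" is not a published parameter, so it is operationalised as
`min_anchors = 3` and `min_span = 1 Mb` on both genomes, both configurable
and echoed into output headers. Micro-rearrangements are tolerated inside
a block: a run of foreign (out-of-order or opposite-orientation) anchors
interrupting a block only splits it when the run's extent exceeds
`micro_tolerance` (default 200 kb). A 2 Mb inversion therefore splits its
host block into +/−/+ and produces two intrachromosomal EBRs; a single
flipped anchor is skipped over. Finally, blocks overlapping on a genome
are trimmed at the midpoint of the overlap, because EBR detection needs
non-overlapping flanks.

## EBRs, fissions, unions

`detect_ebrs()` sorts blocks along each target chromosome and emits one
EBR per inter-block gap, bounded exactly by the flanking block
coordinates. Chromosome-terminal gaps are not EBRs (the definition
requires a block on each side). An EBR is interchromosomal iff its two
flanks map to different partner chromosomes; abutting blocks with
different partners emit a 1-bp EBR so fission evidence is never silently
dropped. `count_fission_events()` counts partner transitions along each
chromosome — identical to the number of interchromosomal EBRs whenever
gaps are nonzero (a tested invariant).

`merge_ebr_sets()` unions two EBR sets on the same genome: records sharing
at least one base collapse (transitively) into one record spanning the
union interval, with provenance unioned in `sources`. The overlap pair
count is the number of merged groups containing members of both sets;
merging a set with itself reports zero. With one chromosome-level genome
compared against two others, the per-genome union of the two pairwise EBR
sets is exactly this operation — the published worked examples
(58 + 15 with 14 overlaps → 59; 17 + 48 with 10 → 55; 36 + 28 with 27 →
37) are reproduced by `scripts/acceptance.R` and the acceptance tests.

On each chromosome, HSB spans, EBR spans and the two terminal gaps tile
the chromosome exactly — no overlap, no hole — and the suite asserts this
on fuzzed simulations. The only deliberate exception is the 1-bp EBR
emitted at an abutting fission junction, which overlaps the right-hand
block by construction.

## Feature statistics

`compare_ebr_features()` tiles each chromosome into fixed windows (default
100 kb), measures gene density (midpoint counting, genes/Mb), GC fraction
(N excluded from the denominator) and repeat coverage per window, and runs
a Mann-Whitney U test of EBR-overlapping windows against a baseline — per
chromosome and pooled genome-wide. The baseline is a genuine design
choice the source methods leave open, so both readings are implemented:

* `baseline = "all"` (default): all windows of the chromosome, the
  literal "EBRs versus the whole chromosome". Because the EBR windows are
  then part of the baseline sample, the test is *conservative* — under the
  null its type-I error is well below nominal (~0.015 at α = 0.05 in our
  calibration runs).
* `baseline = "complement"`: the non-EBR windows, giving disjoint samples
  and calibrated type-I error (0.03–0.06 across seeds). This is the
  variant the calibration test in the suite exercises, since p-values can
  only be uniform under a null with disjoint samples.

`mann_whitney_u()` computes U as pairs with x > y plus half the ties. The
exact method uses the enumerated null (tie-free, n1·n2 ≤ 10 000; it falls
back to the tie-corrected normal approximation with continuity correction
otherwise). Both routes are tested against full enumeration and against
`wilcox.test()`. The direction of the test is reported rather than
assumed: the source analysis does not state sidedness, so two-sided is
the default.

`repeat_family_enrichment()` reports, per repeat family, the fold change
of its coverage fraction in EBR bases over its genome-wide fraction, with
a permutation p-value from ≥ 1000 (configurable) random placements of a
length-matched region set on the same karyotype.
`geneset_overrepresentation()` is an upper-tail hypergeometric test per
term with Benjamini–Hochberg adjustment across terms; the background
universe is a required explicit input (the original analysis ran through a
web service whose universe is unstated). Gene membership in regions uses
the ≥ 1-bp overlap rule (`genes_in_regions()`), while densities use
midpoint counting — the asymmetry avoids double-counting genes across
tiled windows.

## Scaffold-to-chromosome reconstruction

`assign_by_coverage()` normalises each flow-sorted library column by its
median depth (libraries are sequenced to very different depths) and
assigns a scaffold when the best/second-best ratio reaches `min_ratio`
(default 3). Mixed libraries — two chromosomes sorted together — are kept
as joint labels and resolved by `resolve_with_reference()`: a scaffold
goes to the member chromosome whose corresponding reference chromosome
carries ≥ 60% of its aligned HSB span. The reference-to-target chromosome
correspondence is an explicit input table, not an inference.
`order_by_reference()` sorts scaffolds by the span-weighted median
reference coordinate of their HSBs and calls orientation only when ≥ 70%
of aligned span agrees, otherwise `"unknown"` — mirroring the honest state
of scaffolds whose strand the evidence cannot settle. `emit_layout()`
materialises the result as AGP v2.1 plus an ordered FASTA (minus-strand
scaffolds reverse-complemented, 100-N gaps); AGP round-trips through
`read_agp()`/`agp_to_placements()` identically.

## Numerical and degenerate-input choices

* Zero-length inter-block gaps with different partners → 1-bp EBR;
  with the same partner → nothing.
* All-N regions have undefined GC and return `NA` with a warning.
* Families absent genome-wide have undefined fold change (`NA`).
* Terms with zero overlap report p = 1 (upper-tail convention).
* Empty anchor sets, empty EBR sets and single-block chromosomes return
  empty results, not errors; malformed ortholog rows warn and drop (or
  abort in strict mode).
* All randomness flows from explicit `seed` arguments; identical seeds
  give byte-identical FASTA/BED/TSV outputs.

## What the tests do and do not show

The simulator plants rearrangements, repeat-biased breakpoints and flank
enrichment, and the suite demonstrates exact recovery: fission counts,
truth breakpoints inside interchromosomal EBRs, enrichment direction and
LINE-L1 ranking in ≥ 90% of seeded replicates, calibrated type-I error
under the null, and exact scaffold-layout reconstruction. What passing
does *not* show: performance on real alignments (no indels or inexact
matching in the sequence model), robustness to assembly error, or any
claim about specific published HSB/EBR counts on real genomes — those
depend on unpublished alignment-tool parameters and are explicitly not
implementation targets. Problem sizes in tests (genomes of tens of Mb,
hundreds of anchors) were chosen as the smallest at which every contract
is informative.

## A short worked example

```{r example, eval = FALSE}
anc <- simulate_ancestor(n_chromosomes = 4, length_mean = 5e6,
                         length_cv = 0, gene_placement = "regular",
                         gene_rate = 5, with_sequence = FALSE, seed = 7)
sim <- apply_rearrangements(
  anc, plan = list(list(kind = "fission", chrom = "chr1", pos = 2.5e6),
                   list(kind = "inversion", chrom = "chr2",
                        start = 1.1e6, end = 3.4e6)))
hsbs <- sim$truth$ortholog_map |> emit_anchors() |>
  chain_anchors(min_span = 5e5)
detect_ebrs(hsbs, target = "a") |>
  select(chrom, start, end, partner_left, partner_right, kind)
count_fission_events(hsbs, target = "a")
```

The fission shows up as one interchromosomal EBR at the cut site; the
inversion as a split +/−/+ block with two intrachromosomal EBRs at its
boundaries.
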