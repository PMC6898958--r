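# breakscape

Comparative synteny analysis for chromosome-level genomes: chain orthology
anchors into large-scale **homologous synteny blocks (HSBs)**, detect
**evolutionary breakpoint regions (EBRs)** and interchromosomal fission
events, merge EBR sets across pairwise comparisons, and test EBRs for
genomic-feature and gene-set enrichment. A built-in karyotype
rearrangement simulator (fission, fusion, inversion, translocation) with
recorded ground-truth breakpoints makes every stage verifiable, and a
scaffolding module reconstructs chromosome-level layouts from
flow-sorted-chromosome coverage plus reference synteny, emitting AGP v2.1
and ordered FASTA.

## Who this is for

Comparative genomicists studying karyotype evolution — e.g. carnivore
genomes, where a conserved cat-like karyotype (2n = 38) and a heavily
reshuffled dog karyotype (2n = 78) bracket species like the giant panda
(2n = 42) — and anyone who needs a tested, scriptable implementation of
the HSB → EBR → enrichment chain at desk scale.

## The core model

* An **anchor** is an orthologous correspondence between an interval on
  genome A and one on genome B, with orientation (strand product for gene
  pairs) and a weight (span).
* An **HSB** is a score-maximal chain of collinear anchors per
  (chromosome pair, orientation) stratum, found by weighted
  longest-increasing-subsequence dynamic programming with a gap cap on
  both genomes; internal micro-rearrangements up to `micro_tolerance`
  (default 200 kb) are absorbed rather than splitting the block.
  "Large-scale" means `min_anchors >= 3` and `min_span >= 1 Mb` (both
  configurable).
* An **EBR** is the interval between two adjacent HSBs on the target
  genome, demarcated exactly by their end coordinates; it is
  *interchromosomal* iff the flanking blocks map to different partner
  chromosomes — the footprint of a chromosome fission. Fission events are
  counted as partner transitions along each chromosome.
* EBR sets from different comparisons are merged by interval union
  (>= 1 shared bp, transitive), and EBRs are tested for elevated gene
  density, GC and repeat coverage with Mann-Whitney U tests of 100-kb
  windows, for repeat-family enrichment with permutation p-values, and
  for gene-set overrepresentation with hypergeometric tests +
  Benjamini-Hochberg.

Everything is tibble-in / tibble-out and pipes cleanly; `autoplot()`
methods cover HSB sets, EBR sets and feature-test results, and
`tidy()`/`glance()` summarise pipeline runs.

## Worked example

```r
library(breakscape)
library(dplyr)

anc <- simulate_ancestor(n_chromosomes = 4, length_mean = 5e6,
                         length_cv = 0, gene_placement = "regular",
                         gene_rate = 5, with_sequence = FALSE, seed = 7)
sim <- apply_rearrangements(
  anc, plan = list(list(kind = "fission",  chrom = "chr1", pos = 2.5e6),
                   list(kind = "inversion", chrom = "chr2",
                        start = 1.1e6, end = 3.4e6),
                   list(kind = "fission",  chrom = "chr3", pos = 1.9e6)))

hsbs <- sim$truth$ortholog_map |> emit_anchors() |> chain_anchors(min_span = 5e5)
detect_ebrs(hsbs, target = "a") |>
  select(chrom, start, end, partner_left, partner_right, kind)
#> # A tibble: 4 × 6
#>   chrom   start     end partner_left partner_right kind
#>   <chr>   <dbl>   <dbl> <chr>        <chr>         <chr>
#> 1 chr1  2311000 2500000 chr1.1       chr1.2        interchromosomal
#> 2 chr2   911000 1100000 chr2         chr2          intrachromosomal
#> 3 chr2  3311000 3500000 chr2         chr2          intrachromosomal
#> 4 chr3  1711000 1900000 chr3.1       chr3.2        interchromosomal

count_fission_events(hsbs, target = "a")
#> [1] 2
```

The two planted fissions surface as interchromosomal EBRs whose intervals
contain the true cut sites (2.5 Mb on chr1, 1.9 Mb on chr3); the 2.3 Mb
inversion splits its block and leaves two intrachromosomal EBRs at its
boundaries. `run_pipeline(default_config())` drives the full
simulate → anchors → chain → EBR → merge → enrichment loop for three
derived genomes (six pairwise comparisons) and returns a run report.

## Layout

* `R/` — simulator, anchors, chaining, breakpoints, features, scaffolding,
  pipeline, I/O (FASTA via Biostrings; BED/GFF3 via rtracklayer; AGP
  reader/writer included).
* `tests/testthat/` — unit and property tests with independent oracles
  (brute-force match finding, exhaustive chain search, full Mann-Whitney
  and hypergeometric enumeration), plus an acceptance suite covering
  breakpoint recovery, statistical calibration and scaffold
  reconstruction.
* `vignettes/breakscape-methods.Rmd` — the models, parameter choices and
  their rationale, and known limitations.
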