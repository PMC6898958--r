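Package: breakscape
Title: Synteny Block Chaining and Evolutionary Breakpoint Region Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of chromosome-level genome
    assemblies: chaining of orthology anchors into large-scale homologous
    synteny blocks (HSBs), detection of evolutionary breakpoint regions
    (EBRs) and interchromosomal fission events, merging of EBR sets across
    pairwise genome comparisons, Mann-Whitney tests of genomic features
    (gene density, GC content, repeat coverage) in EBRs versus the whole
    genome, repeat-family and hypergeometric gene-set enrichment, and
    reference-assisted assignment and ordering of scaffolds into
    chromosomes. Includes a karyotype rearrangement simulator (fission,
    fusion, inversion, translocation) with recorded ground-truth
    breakpoints for validating breakpoint recovery end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    methods,
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
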