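# Simulator: determinism, composition targets, event arithmetic and
# conservation laws.

test_that("ancestor simulation is reproducible and hits GC/repeat targets", {
  a1 <- simulate_ancestor(n_chromosomes = 2, length_mean = 1e6,
                          length_cv = 0, gene_rate = 10,
                          repeat_mix = c("LINE-L1" = 0.3),
                          gc_target = 0.5, seed = 7)
  a2 <- simulate_ancestor(n_chromosomes = 2, length_mean = 1e6,
                          length_cv = 0, gene_rate = 10,
                          repeat_mix = c("LINE-L1" = 0.3),
                          gc_target = 0.5, seed = 7)
  expect_identical(as.character(a1$karyotype$seqs),
                   as.character(a2$karyotype$seqs))
  expect_identical(a1$features, a2$features)
  expect_equal(nrow(a1$karyotype$chromosomes), 2)

  n_genes <- sum(a1$features$category == "gene")
  expect_gt(n_genes, 10)
  expect_lt(n_genes, 35)

  # genome-wide GC within +/- 0.02 of target on a 2 Mb genome
  gc <- sum(Biostrings::letterFrequency(a1$karyotype$seqs, c("G", "C"))) /
    sum(a1$karyotype$chromosomes$length)
  expect_gt(gc, 0.48)
  expect_lt(gc, 0.52)

  # LINE-L1 coverage fraction near the requested 0.3
  reps <- a1$features[a1$features$category == "repeat", ]
  frac <- sum(reps$end - reps$start) / sum(a1$karyotype$chromosomes$length)
  expect_gt(frac, 0.27)
  expect_lt(frac, 0.33)

  # genes never overlap genes; repeats never overlap repeats
  for (cat in c("gene", "repeat")) {
    f <- a1$features[a1$features$category == cat, ]
    f <- f[order(f$chrom, f$start), ]
    same <- f$chrom[-1] == f$chrom[-nrow(f)]
    expect_true(all(f$start[-1][same] >= f$end[-nrow(f)][same]))
  }
})

test_that("invalid simulator inputs are rejected", {
  expect_error(simulate_ancestor(n_chromosomes = 0), "positive")
  expect_error(simulate_ancestor(repeat_mix = c("LINE-L1" = 0.7,
                                                SINE = 0.5)), "sum")
  expect_error(simulate_ancestor(gc_target = 1.2), "gc_target")
})

test_that("fission splits lengths exactly and conserves total length", {
  g <- toy_genome(c(chr1 = 1e7))
  sim <- apply_rearrangements(
    g, plan = list(list(kind = "fission", chrom = "chr1", pos = 4e6)))
  expect_equal(sort(sim$derived$karyotype$chromosomes$length), c(4e6, 6e6))
  expect_equal(sum(sim$derived$karyotype$chromosomes$length), 1e7)
  expect_equal(nrow(sim$truth$breakpoints), 1)
  expect_equal(sim$truth$breakpoints$start, 4e6 - 1)
  expect_equal(sim$truth$breakpoints$end, 4e6 + 1)
})

test_that("inversion relocates genes by mirror arithmetic and flips strand", {
  g <- toy_genome(c(chr1 = 1e7),
                  genes = toy_genes("chr1", 3.0e6, 3.1e6, "+", "gX"))
  sim <- apply_rearrangements(
    g, plan = list(list(kind = "inversion", chrom = "chr1",
                        start = 2e6, end = 5e6)))
  gene <- sim$derived$features[sim$derived$features$name == "gX", ]
  # new_start = inv_start + (inv_end - old_end)
  expect_equal(gene$start, 2e6 + (5e6 - 3.1e6))
  expect_equal(gene$end, 2e6 + (5e6 - 3.0e6))
  expect_equal(gene$strand, "-")
  expect_equal(sum(sim$derived$karyotype$chromosomes$length), 1e7)
})

test_that("12 fissions of a 10-chromosome ancestor give 22 chromosomes", {
  anc <- simulate_ancestor(n_chromosomes = 10, length_mean = 1e6,
                           length_cv = 0, gene_rate = 3, repeat_mix = NULL,
                           with_sequence = FALSE, seed = 3)
  sim <- apply_rearrangements(anc, n_events = 12,
                              rates = c(fission = 1, fusion = 0,
                                        inversion = 0, translocation = 0),
                              seed = 4)
  expect_equal(nrow(sim$derived$karyotype$chromosomes), 22)
  expect_equal(sum(sim$derived$karyotype$chromosomes$length),
               sum(anc$karyotype$chromosomes$length))
  expect_equal(nrow(sim$truth$breakpoints), 12)
  # genes survive intact
  expect_equal(sum(sim$derived$features$category == "gene"),
               sum(anc$features$category == "gene"))
})

test_that("fission followed by fusion of its products restores the sequence", {
  anc <- simulate_ancestor(n_chromosomes = 1, length_mean = 2e5,
                           length_cv = 0, gene_rate = 10,
                           repeat_mix = c(SINE = 0.1), gc_target = 0.45,
                           seed = 11)
  sim <- apply_rearrangements(
    anc, plan = list(list(kind = "fission", chrom = "chr1", pos = 9e4),
                     list(kind = "fusion",
                          chroms = c("chr1.1", "chr1.2"))))
  expect_equal(nrow(sim$derived$karyotype$chromosomes), 1)
  expect_identical(as.character(sim$derived$karyotype$seqs[[1]]),
                   as.character(anc$karyotype$seqs[[1]]))
})

test_that("translocation exchanges tails and conserves genome length", {
  g <- toy_genome(c(chr1 = 5e6, chr2 = 3e6))
  sim <- apply_rearrangements(
    g, plan = list(list(kind = "translocation",
                        chroms = c("chr1", "chr2"), pos = c(2e6, 1e6))))
  lens <- sort(sim$derived$karyotype$chromosomes$length)
  expect_equal(lens, sort(c(2e6 + 2e6, 1e6 + 3e6)))
  expect_equal(nrow(sim$truth$breakpoints), 2)
})

test_that("breakpoints inside gene bodies are rejected by default", {
  g <- toy_genome(c(chr1 = 1e6), genes = toy_genes("chr1", 4e5, 5e5))
  expect_error(apply_rearrangements(
    g, plan = list(list(kind = "fission", chrom = "chr1", pos = 4.5e5))),
    "gene body")
  expect_error(apply_rearrangements(
    g, plan = list(list(kind = "fission", chrom = "chr1", pos = 2e6))),
    "outside")
})

test_that("emit_anchors honours dropout, jitter bounds and micro-inversions", {
  anc <- simulate_ancestor(n_chromosomes = 2, length_mean = 5e6,
                           length_cv = 0, gene_rate = 100, repeat_mix = NULL,
                           with_sequence = FALSE, seed = 5)
  sim <- apply_rearrangements(anc, n_events = 2,
                              rates = c(fission = 1, fusion = 0,
                                        inversion = 0, translocation = 0),
                              seed = 6)
  om <- sim$truth$ortholog_map

  # identity case: anchors exactly at gene coordinates
  a0 <- emit_anchors(om)
  expect_equal(nrow(a0), nrow(om))
  expect_equal(a0$start_a, om$start_a)
  expect_equal(a0$start_b, om$start_b)

  # dropout: binomial count near (1 - dropout) * n
  om1k <- om[rep(seq_len(nrow(om)), length.out = 1000), ]
  a <- emit_anchors(om1k, dropout = 0.2, seed = 42)
  expect_gte(nrow(a), 760)
  expect_lte(nrow(a), 840)

  # micro-inversions flip orientation only
  a5 <- emit_anchors(om, micro_inversion_rate = 0.5, seed = 1)
  flipped <- mean(a5$orientation != a0$orientation)
  expect_gt(flipped, 0.3)
  expect_lt(flipped, 0.7)
  expect_equal(a5$start_a, a0$start_a)

  # jitter never leaves the chromosome
  aj <- emit_anchors(om, jitter_sd = 5e4,
                     karyotype_a = sim$ancestor$karyotype,
                     karyotype_b = sim$derived$karyotype, seed = 2)
  expect_true(all(aj$start_a >= 0 & aj$start_a < aj$end_a))
  lb <- sim$derived$karyotype$chromosomes$length[
    match(aj$chrom_b, sim$derived$karyotype$chromosomes$chrom)]
  expect_true(all(aj$end_b <= lb))

  expect_error(emit_anchors(om[0, ]), "empty")
})

test_that("byte-identical outputs for identical seeds", {
  run_once <- function() {
    anc <- simulate_ancestor(n_chromosomes = 1, length_mean = 1e5,
                             length_cv = 0, gene_rate = 20,
                             repeat_mix = c(SINE = 0.1), seed = 99)
    fa <- tempfile(fileext = ".fa"); bed <- tempfile(fileext = ".bed")
    write_fasta(anc$karyotype, fa)
    write_intervals(anc$features, bed, "bed")
    list(fa = readLines(fa), bed = readLines(bed))
  }
  expect_identical(run_once(), run_once())
})
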