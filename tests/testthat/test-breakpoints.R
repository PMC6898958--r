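# EBR detection, fission counting, set merging and summaries.

mk_hsbs <- function(chrom_a, start_a, end_a, chrom_b,
                    start_b = start_a, end_b = end_a, orientation = "+") {
  tibble::tibble(
    hsb_id = sprintf("h%03d", seq_along(start_a)),
    chrom_a = chrom_a, start_a = start_a, end_a = end_a,
    chrom_b = chrom_b, start_b = start_b, end_b = end_b,
    orientation = orientation, n_anchors = 5L,
    span_a = end_a - start_a, span_b = end_b - start_b,
    score = end_a - start_a, anchor_ids = replicate(length(start_a),
                                                    character(0),
                                                    simplify = FALSE))
}

mk_ebrs <- function(id, chrom, start, end, genome_id = "G") {
  tibble::tibble(ebr_id = id, genome_id = genome_id, chrom = chrom,
                 start = start, end = end)
}

test_that("the gap between two HSBs with different partners is one
           interchromosomal EBR; terminal gaps are not EBRs", {
  h <- mk_hsbs("chr1", c(0, 12e6), c(10e6, 20e6), c("dogX", "dogY"))
  e <- detect_ebrs(h, "a")
  expect_equal(nrow(e), 1)
  expect_equal(e$start, 10e6)
  expect_equal(e$end, 12e6)
  expect_equal(e$kind, "interchromosomal")
  expect_equal(e$partner_left, "dogX")
  expect_equal(e$partner_right, "dogY")

  single <- detect_ebrs(mk_hsbs("chr1", 0, 1e6, "dogX"), "a")
  expect_equal(nrow(single), 0)
})

test_that("abutting HSBs with different partners emit a 1-bp EBR", {
  h <- mk_hsbs("chr1", c(0, 10e6), c(10e6, 20e6), c("dogX", "dogY"))
  e <- detect_ebrs(h, "a")
  expect_equal(nrow(e), 1)
  expect_equal(e$end - e$start, 1)
  # same partner, abutting: nothing to report
  h2 <- mk_hsbs("chr1", c(0, 10e6), c(10e6, 20e6), c("dogX", "dogX"))
  expect_equal(nrow(detect_ebrs(h2, "a")), 0)
})

test_that("overlapping HSBs on the target are rejected with the pair named", {
  h <- mk_hsbs("chr1", c(0, 5e6), c(8e6, 20e6), c("dogX", "dogY"))
  expect_error(detect_ebrs(h, "a"), "h001.*h002")
})

test_that("fission events count partner transitions per chromosome", {
  h <- mk_hsbs("chr1", c(0, 4e6, 8e6), c(3e6, 7e6, 12e6),
               c("X", "Y", "X"))
  expect_equal(count_fission_events(h, "a"), 2L)
  h2 <- mk_hsbs("chr1", c(0, 4e6, 8e6), c(3e6, 7e6, 12e6), "X")
  expect_equal(count_fission_events(h2, "a"), 0L)
  expect_equal(count_fission_events(h[0, ], "a"), 0L)
})

test_that("fission count equals interchromosomal EBR count with nonzero
           gaps", {
  set.seed(13)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    bounds <- sort(sample(seq(0, 50e6, by = 1e6), 2 * n))
    h <- mk_hsbs("chr1", bounds[seq(1, 2 * n, 2)], bounds[seq(2, 2 * n, 2)],
                 sample(c("P", "Q", "R"), n, replace = TRUE))
    h <- h[h$end_a > h$start_a, ]
    e <- detect_ebrs(h, "a")
    expect_equal(count_fission_events(h, "a"),
                 sum(e$kind == "interchromosomal"))
  }
})

test_that("interval-union merging follows the worked examples", {
  r <- merge_ebr_sets(mk_ebrs("a1", "c1", 10e6, 12e6),
                      mk_ebrs("b1", "c1", 11e6, 13e6))
  expect_equal(nrow(r$ebrs), 1)
  expect_equal(r$ebrs$start, 10e6)
  expect_equal(r$ebrs$end, 13e6)
  expect_equal(r$overlap_pair_count, 1L)

  r2 <- merge_ebr_sets(mk_ebrs(paste0("a", 1:3), "c1",
                               c(0, 10e6, 20e6), c(1e6, 11e6, 21e6)),
                       mk_ebrs(paste0("b", 1:2), "c1",
                               c(30e6, 40e6), c(31e6, 41e6)))
  expect_equal(nrow(r2$ebrs), 5)
  expect_equal(r2$overlap_pair_count, 0L)

  expect_error(merge_ebr_sets(mk_ebrs("a1", "c1", 0, 1, "G1"),
                              mk_ebrs("b1", "c1", 0, 1, "G2")),
               "different genomes")
})

test_that("merge is commutative and self-merge collapses with zero
           cross-set pairs", {
  set.seed(5)
  x <- mk_ebrs(sprintf("x%02d", 1:10), "c1",
               sort(sample(seq(0, 90e6, 1e5), 10)), NA)
  x$end <- x$start + sample(seq(5e4, 2e6, 5e4), 10)
  y <- mk_ebrs(sprintf("y%02d", 1:6), "c1",
               sort(sample(seq(0, 90e6, 1e5), 6)), NA)
  y$end <- y$start + sample(seq(5e4, 2e6, 5e4), 6)
  ab <- merge_ebr_sets(x, y)
  ba <- merge_ebr_sets(y, x)
  expect_equal(as.data.frame(ab$ebrs), as.data.frame(ba$ebrs))
  expect_equal(ab$overlap_pair_count, ba$overlap_pair_count)
  self <- merge_ebr_sets(x, x)
  expect_equal(nrow(self$ebrs), nrow(x))
  expect_equal(self$overlap_pair_count, 0L)
})

test_that("ebr_summary arithmetic", {
  e <- mk_ebrs(paste0("e", 1:3), c("c1", "c1", "c2"),
               c(0, 5e6, 0), c(1e6, 7e6, 3e6))
  s <- ebr_summary(e)
  expect_equal(s$stats$n, 3)
  expect_equal(s$stats$total_span, 6e6)
  expect_equal(s$stats$mean_length, 2e6)
  expect_equal(s$per_chromosome$n[s$per_chromosome$chrom == "c1"], 2L)
  one <- ebr_summary(e[1, ])
  expect_equal(one$stats$min_length, one$stats$max_length)
  zero <- ebr_summary(e[0, ])
  expect_equal(zero$stats$n, 0L)
})

test_that("HSBs, EBRs and terminal gaps tile each chromosome exactly", {
  anc <- simulate_ancestor(n_chromosomes = 4, length_mean = 6e6,
                           length_cv = 0, gene_rate = 8, repeat_mix = NULL,
                           with_sequence = FALSE, seed = 21)
  sim <- apply_rearrangements(anc, n_events = 6,
                              rates = c(fission = 2, inversion = 1,
                                        translocation = 1, fusion = 0),
                              seed = 22)
  a <- emit_anchors(sim$truth$ortholog_map)
  h <- chain_anchors(a, min_span = 5e5)
  e <- detect_ebrs(h, "a")
  for (cn in unique(h$chrom_a)) {
    hs <- h[h$chrom_a == cn, ]
    hs <- hs[order(hs$start_a), ]
    es <- e[e$chrom == cn, ]
    L <- anc$karyotype$chromosomes$length[
      anc$karyotype$chromosomes$chrom == cn]
    pieces <- rbind(cbind(hs$start_a, hs$end_a),
                    if (nrow(es)) cbind(es$start, es$end))
    pieces <- pieces[order(pieces[, 1]), , drop = FALSE]
    # no overlap, no hole between first and last HSB
    expect_true(all(pieces[-1, 1] == pieces[-nrow(pieces), 2]))
    expect_gte(pieces[1, 1], 0)
    expect_lte(pieces[nrow(pieces), 2], L)
  }
})
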