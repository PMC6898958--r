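# Coverage-based assignment, reference-assisted resolution/ordering, and
# AGP materialization.

test_that("coverage assignment: dominant signal, ambiguity and scale
           invariance", {
  # mostly-background columns, as produced by real sorted libraries, so
  # the per-library median normalizes to the background depth
  m <- tibble::tibble(scaffold = paste0("s", 1:6),
                      lib1 = c(100, 50, 0, 1, 1, 1),
                      lib2 = c(1, 45, 0, 80, 1, 2),
                      lib3 = c(2, 1, 0, 1, 60, 1))
  expect_warning(r <- assign_by_coverage(m, min_ratio = 3), "all-zero")
  expect_equal(r$library[r$scaffold == "s1"], "lib1")
  expect_equal(r$library[r$scaffold == "s4"], "lib2")
  expect_equal(r$library[r$scaffold == "s5"], "lib3")
  expect_true(r$ambiguous[r$scaffold == "s2"])  # 50 vs 45: below 3x
  expect_true(r$ambiguous[r$scaffold == "s3"])

  m2 <- m; m2$lib1 <- m2$lib1 * 37
  expect_warning(r2 <- assign_by_coverage(m2, min_ratio = 3))
  expect_equal(r$library, r2$library)
  expect_equal(r$ambiguous, r2$ambiguous)
  expect_error(assign_by_coverage(m, min_ratio = 1), "min_ratio")
})

test_that("reference synteny resolves mixed libraries by span majority", {
  asg <- tibble::tibble(scaffold = c("s1", "s2"),
                        library = c("chr10+chr11", "chr10+chr11"),
                        confidence = 10, ambiguous = FALSE)
  hsbs <- tibble::tibble(
    chrom_a = c("s1", "s1", "s2", "s2"),
    chrom_b = c("refC", "refD", "refC", "refD"),
    span_a = c(95, 5, 50, 50))
  corr <- tibble::tibble(ref_chrom = c("refC", "refD"),
                         target_chrom = c("chr10", "chr11"))
  r <- resolve_with_reference(asg, hsbs, corr)
  expect_equal(r$chromosome[r$scaffold == "s1"], "chr10")
  expect_true(is.na(r$chromosome[r$scaffold == "s2"]))  # 50/50 split
})

test_that("ordering follows span-weighted median reference position and
           majority orientation", {
  asg <- tibble::tibble(scaffold = c("s1", "s2", "s3"), chromosome = "chr1")
  hsbs <- tibble::tibble(
    chrom_a = c("s1", "s2", "s3", "s3"),
    chrom_b = "ref1",
    start_b = c(30e6, 10e6, 50e6, 52e6), end_b = c(31e6, 11e6, 51e6, 53e6),
    span_a = c(1e6, 1e6, 8e5, 2e5),
    orientation = c("+", "+", "-", "+"))
  pl <- order_by_reference(asg, hsbs)
  expect_equal(pl$scaffold[order(pl$rank)], c("s2", "s1", "s3"))
  expect_equal(pl$orientation[pl$scaffold == "s3"], "-")  # 80% minus span
  hsbs$span_a[3] <- 3e5  # 60% minus: below the 70% majority
  pl2 <- order_by_reference(asg, hsbs)
  expect_equal(pl2$orientation[pl2$scaffold == "s3"], "unknown")
})

test_that("emit_layout arithmetic, minus-strand handling and AGP round
           trip", {
  seqs <- Biostrings::DNAStringSet(c(s1 = strrep("ACGT", 25),
                                     s2 = strrep("GGCA", 25)))
  sc <- karyotype("sc", tibble::tibble(chrom = c("s1", "s2"),
                                       length = c(100, 100)), seqs)
  pl <- tibble::tibble(scaffold = c("s1", "s2"), chromosome = "chr1",
                       rank = 1:2, orientation = c("+", "-"))
  lay <- emit_layout(pl, sc, gap_size = 100)
  expect_equal(lay$karyotype$chromosomes$length, 300)
  seq <- as.character(lay$karyotype$seqs[[1]])
  expect_equal(substr(seq, 1, 100), strrep("ACGT", 25))
  expect_equal(substr(seq, 101, 200), strrep("N", 100))
  expect_equal(substr(seq, 201, 300),
               as.character(Biostrings::reverseComplement(seqs[["s2"]])))
  expect_equal(lay$agp$orientation[lay$agp$component_type == "W"],
               c("+", "-"))

  tf <- withr::local_tempfile(fileext = ".agp")
  write_agp(lay$agp, tf)
  expect_equal(as.data.frame(read_agp(tf)), as.data.frame(lay$agp))
  expect_equal(as.data.frame(agp_to_placements(lay$agp)),
               as.data.frame(pl))
  expect_error(emit_layout(pl[c(1, 1), ], sc), "duplicate")
})

test_that("shred-and-recover reconstructs the simulated chromosomes", {
  anc <- simulate_ancestor(n_chromosomes = 3, length_mean = 1.5e6,
                           length_cv = 0.1, gene_rate = 60,
                           gene_placement = "regular",
                           repeat_mix = NULL, with_sequence = TRUE,
                           seed = 15)
  sh <- shred_karyotype(anc$karyotype, pieces_per_chrom = 5,
                        flip_fraction = 0.4, min_piece = 1e5, seed = 16)
  cov <- simulate_coverage_matrix(sh$truth,
                                  merged_libraries = list(c("chr2", "chr3")),
                                  seed = 17)
  asg <- assign_by_coverage(cov)
  pairs <- scaffold_reference_pairs(anc$features, sh$truth)
  anchors <- anchors_from_orthologs(pairs)
  hsbs <- chain_anchors(anchors, max_gap = 2e6, min_anchors = 1,
                        min_span = 1e3, micro_tolerance = 2e5)
  corr <- tibble::tibble(ref_chrom = paste0("chr", 1:3),
                         target_chrom = paste0("chr", 1:3))
  res <- resolve_with_reference(asg, hsbs, corr)
  truth_map <- sh$truth[, c("scaffold", "chrom")]
  j <- merge(res[!is.na(res$chromosome), ], truth_map, by = "scaffold")
  expect_true(all(j$chromosome == j$chrom))

  pl <- order_by_reference(res, hsbs)
  chk <- merge(pl, sh$truth, by = "scaffold")
  for (cn in unique(chk$chromosome)) {
    sub <- chk[chk$chromosome == cn, ]
    expect_equal(cor(sub$rank.x, sub$rank.y, method = "kendall"), 1)
  }
  lay <- emit_layout(pl, sh$karyotype, genome_id = "rebuilt")
  for (cn in paste0("chr", 1:3)) {
    rebuilt <- gsub("N", "", as.character(lay$karyotype$seqs[[cn]]))
    expect_identical(rebuilt, as.character(anc$karyotype$seqs[[cn]]))
  }
})
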