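# Feature measurement and enrichment statistics.

test_that("gc_content worked examples and N handling", {
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("AAAA"), 0)
  expect_equal(gc_content("ATGN"), 1 / 3)
  expect_warning(v <- gc_content("NNNN"), "all-N")
  expect_true(is.na(v))
  seqs <- Biostrings::DNAStringSet(c(c1 = "ATGCATGC"))
  expect_equal(gc_content(seqs, tibble::tibble(chrom = "c1", start = 0,
                                               end = 4)), 0.5)
  expect_error(gc_content(seqs, tibble::tibble(chrom = "c1", start = 0,
                                               end = 99)), "outside")
})

test_that("region_density matches the per-base oracle on toy data", {
  g <- toy_genome(c(c1 = 1e4),
                  genes = toy_genes("c1", c(100, 2000, 4000),
                                    c(600, 2500, 4800)))
  reg <- tibble::tibble(chrom = "c1", start = 0, end = 1e4)
  expect_equal(region_density(g$features, reg, "count_per_mb"),
               3 / (1e4 / 1e6))
  set.seed(88)
  for (rep in 1:10) {
    n <- sample(3:12, 1)
    s <- sort(sample(0:9000, n))
    feats <- toy_genes("c1", s, pmin(s + sample(50:900, n, replace = TRUE),
                                     1e4))
    r <- tibble::tibble(chrom = "c1", start = sample(0:4000, 1), end = NA)
    r$end <- r$start + sample(1000:5000, 1)
    for (mode in c("count_per_mb", "coverage_fraction")) {
      expect_equal(region_density(feats, r, mode),
                   oracle_region_value(feats, r, mode))
    }
  }
  expect_error(region_density(g$features,
                              tibble::tibble(chrom = "c1", start = 5,
                                             end = 5), "count_per_mb"),
               "zero-length")
})

test_that("Mann-Whitney U: worked example, symmetry and tie handling", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)
  expect_equal(r$method, "exact")

  # U(x, y) + U(y, x) = n1 * n2
  set.seed(9)
  for (rep in 1:10) {
    x <- rnorm(sample(2:8, 1)); y <- rnorm(sample(2:8, 1))
    u1 <- mann_whitney_u(x, y)$statistic
    u2 <- mann_whitney_u(y, x)$statistic
    expect_equal(u1 + u2, length(x) * length(y))
  }

  # identical samples: U = n1*n2/2, p = 1 under the normal method
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3), method = "normal")
  expect_equal(same$statistic, 4.5)
  expect_equal(same$p_value, 1)
  expect_equal(same$direction, "none")

  expect_warning(tied <- mann_whitney_u(c(1, 1, 2), c(1, 2, 3),
                                        method = "exact"), "ties")
  expect_equal(tied$method, "normal")
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("mann_whitney_u agrees with wilcox.test and full enumeration", {
  set.seed(123)
  for (rep in 1:20) {
    n1 <- sample(2:7, 1); n2 <- sample(2:7, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    ours <- mann_whitney_u(x, y, method = "exact")
    wt <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$statistic, unname(wt$statistic))
    expect_equal(ours$p_value, wt$p.value)
    expect_equal(ours$p_value, oracle_mwu_p(x, y))
    # tie-corrected normal approximation with continuity correction
    wtn <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(mann_whitney_u(x, y, method = "normal")$p_value,
                 wtn$p.value)
  }
})

test_that("compare_ebr_features: identical windows give p = 1 and empty
           overlap warns", {
  g <- toy_genome(c(c1 = 1e6))
  wins <- tibble::tibble(chrom = "c1", start = seq(0, 9e5, 1e5),
                         end = seq(1e5, 1e6, 1e5),
                         gene_density = 5, repeat_cov = 0.2, gc = NA_real_)
  st <- compare_ebr_features(g, tibble::tibble(chrom = "c1", start = 1e5,
                                               end = 3e5),
                             windows = wins, per_chromosome = FALSE)
  expect_true(all(st$p_value == 1))
  expect_warning(
    compare_ebr_features(g, tibble::tibble(chrom = "zz", start = 0, end = 1),
                         windows = wins, per_chromosome = FALSE),
    "no windows")
})

test_that("repeat-family fold changes: ratio and identity cases", {
  reps <- tibble::tibble(
    chrom = "c1", start = c(0, 5e5), end = c(1e5, 5.5e5),
    name = c("r1", "r2"), category = "repeat",
    family = c("LINE-L1", "SINE"), strand = "+")
  kar <- karyotype("G", tibble::tibble(chrom = "c1", length = 1e6))
  # EBRs = whole genome: fold 1 for every family
  whole <- tibble::tibble(chrom = "c1", start = 0, end = 1e6)
  r <- repeat_family_enrichment(reps, whole, kar, n_perm = 10, seed = 1)
  expect_equal(r$fold, c(1, 1))
  # family covering 10% of EBR bases vs 5% genome-wide: fold 2
  reps2 <- tibble::tibble(chrom = "c1", start = 0, end = 5e4, name = "r1",
                          category = "repeat", family = "LINE-L1",
                          strand = "+")
  ebr <- tibble::tibble(chrom = "c1", start = 0, end = 5e5)
  r2 <- repeat_family_enrichment(reps2, ebr, kar, n_perm = 10, seed = 1)
  expect_equal(r2$fold, (5e4 / 5e5) / (5e4 / 1e6))
})

test_that("hypergeometric overrepresentation matches enumeration and BH is
           monotone", {
  universe <- paste0("g", 1:20)
  ann <- list(t5 = paste0("g", 1:5), t8 = paste0("g", 1:8),
              tmiss = paste0("g", 16:20))
  # query of 5 genes sharing 4 with the 5-gene term
  res <- geneset_overrepresentation(c(paste0("g", 1:4), "g6"), ann,
                                    universe)
  expect_equal(res$p_value[res$term == "t5"], 76 / 15504)
  expect_equal(res$p_value[res$term == "t5"],
               oracle_hyper_p(20, 5, 5, 4), tolerance = 1e-12)
  expect_equal(res$p_value[res$term == "tmiss"], 1)
  expect_true(all(res$q_value >= res$p_value - 1e-12))
  expect_true(all(diff(res$q_value[order(res$p_value)]) >= -1e-12))

  # saturation: query = universe
  sat <- geneset_overrepresentation(universe, ann, universe)
  expect_true(all(sat$p_value == 1))
  expect_true(all(sat$overlap == sat$term_size))

  expect_error(geneset_overrepresentation("gX", ann, universe),
               "not in the universe")
  expect_error(geneset_overrepresentation("g1", ann, character(0)), "empty")
})

test_that("genes_in_regions uses the 1-bp half-open overlap rule", {
  g <- toy_genes("c1", c(5, 5, 100), c(10, 9, 200),
                 name = c("in1", "out1", "far"))
  regions <- tibble::tibble(chrom = "c1", start = 9, end = 20)
  expect_equal(genes_in_regions(
    dplyr::bind_rows(g), regions), "in1")
  # per-base oracle on random toys
  set.seed(17)
  for (rep in 1:10) {
    n <- sample(5:15, 1)
    s <- sample(0:900, n)
    gg <- toy_genes("c1", s, s + sample(5:80, n, replace = TRUE))
    r <- tibble::tibble(chrom = "c1", start = sample(0:500, 2), end = NA)
    r$end <- r$start + sample(50:300, 2)
    hit <- vapply(seq_len(nrow(gg)), function(i) {
      any(gg$start[i] < r$end & gg$end[i] > r$start)
    }, logical(1))
    expect_setequal(genes_in_regions(gg, r), unique(gg$name[hit]))
  }
})
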