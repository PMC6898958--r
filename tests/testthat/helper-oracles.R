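# Independent oracles used across the suite. These are deliberately naive
# (quadratic scans, exhaustive enumeration) and must stay independent of
# the implementation paths they check.

# all maximal exact matches by O(n^2 * L) scan over start pairs
oracle_matches <- function(a, b, min_len) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  na <- length(av); nb <- length(bv)
  out <- list()
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      if (i > 1 && j > 1 && av[i - 1] == bv[j - 1] && av[i - 1] != "N") next
      len <- 0
      while (i + len <= na && j + len <= nb &&
             av[i + len] == bv[j + len] && av[i + len] != "N") {
        len <- len + 1
      }
      if (len >= min_len) {
        out[[length(out) + 1]] <- c(i - 1, i - 1 + len, j - 1, j - 1 + len)
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(start_a = numeric(), end_a = numeric(),
                          start_b = numeric(), end_b = numeric()))
  }
  m <- do.call(rbind, out)
  tibble::tibble(start_a = m[, 1], end_a = m[, 2],
                 start_b = m[, 3], end_b = m[, 4]) |>
    dplyr::arrange(start_a, start_b)
}

# exhaustive maximum chain score over all anchor subsets, per stratum
oracle_best_score <- function(anchors, max_gap) {
  best <- 0
  key <- paste(anchors$chrom_a, anchors$chrom_b, anchors$orientation)
  for (st in split(anchors, key)) {
    st <- st[order(st$start_a, st$start_b), ]
    ori <- st$orientation[1]
    n <- nrow(st)
    for (mask in seq_len(2^n - 1)) {
      idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
      sub <- st[idx, ]
      ok <- TRUE
      if (nrow(sub) > 1) {
        for (t in 2:nrow(sub)) {
          j <- t - 1; i <- t
          ok <- sub$start_a[j] < sub$start_a[i] &&
            sub$start_a[i] - sub$end_a[j] <= max_gap
          if (ok) {
            ok <- if (ori == "+") {
              sub$start_b[j] < sub$start_b[i] &&
                sub$start_b[i] - sub$end_b[j] <= max_gap
            } else {
              sub$start_b[i] < sub$start_b[j] &&
                sub$start_b[j] - sub$end_b[i] <= max_gap
            }
          }
          if (!ok) break
        }
      }
      if (ok) best <- max(best, sum(sub$weight))
    }
  }
  best
}

# random anchor instance on 1-2 chromosome pairs with random orientations
random_anchor_instance <- function(n, seed) {
  set.seed(seed)
  span <- sample(5:20, n, replace = TRUE)
  tibble::tibble(
    anchor_id = sprintf("a%03d", seq_len(n)),
    chrom_a = "cA",
    start_a = sample(0:300, n),
    chrom_b = sample(c("cB1", "cB2"), n, replace = TRUE),
    start_b = sample(0:300, n),
    orientation = sample(c("+", "-"), n, replace = TRUE),
    weight = sample(1:50, n, replace = TRUE),
    source = "test") |>
    dplyr::mutate(end_a = start_a + span, end_b = start_b + span) |>
    dplyr::select(anchor_id, chrom_a, start_a, end_a, chrom_b, start_b,
                  end_b, orientation, weight, source)
}

# Mann-Whitney two-sided p by full enumeration of group assignments
oracle_mwu_p <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  cmb <- utils::combn(length(pool), n1)
  u_of <- function(xs, ys) {
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  us <- apply(cmb, 2, function(ix) u_of(pool[ix], pool[-ix]))
  u_obs <- u_of(x, y)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# hypergeometric upper-tail p by enumeration of all query draws
oracle_hyper_p <- function(universe_n, term_n, query_n, k) {
  cmb <- utils::combn(universe_n, query_n)
  mean(apply(cmb, 2, function(d) sum(d <= term_n)) >= k)
}

# per-base feature density / coverage oracle on a small chromosome
oracle_region_value <- function(track, region, mode) {
  f <- track[track$chrom == region$chrom, ]
  if (mode == "count_per_mb") {
    mid <- floor((f$start + f$end) / 2) + 0.5  # midpoint base
    sum((f$start + f$end) / 2 >= region$start &
          (f$start + f$end) / 2 < region$end) /
      ((region$end - region$start) / 1e6)
  } else {
    covered <- rep(FALSE, region$end - region$start)
    for (i in seq_len(nrow(f))) {
      lo <- max(f$start[i], region$start)
      hi <- min(f$end[i], region$end)
      if (hi > lo) covered[(lo - region$start + 1):(hi - region$start)] <- TRUE
    }
    mean(covered)
  }
}

# tiny hand-built genome: karyotype + features usable as `ancestor`
toy_genome <- function(lens = c(chr1 = 1e6), genes = NULL, repeats = NULL,
                       genome_id = "toy") {
  kar <- karyotype(genome_id,
                   tibble::tibble(chrom = names(lens), length = unname(lens)))
  track <- dplyr::bind_rows(genes, repeats)
  if (is.null(track) || !nrow(track)) {
    track <- tibble::tibble(chrom = character(), start = numeric(),
                            end = numeric(), name = character(),
                            category = character(), family = character(),
                            strand = character())
  }
  list(karyotype = kar, features = track, params = list())
}

toy_genes <- function(chrom, start, end, strand = "+",
                      name = sprintf("g%03d", seq_along(start))) {
  tibble::tibble(chrom = chrom, start = start, end = end, name = name,
                 category = "gene", family = NA_character_, strand = strand)
}

# ortholog pairs of scaffolds (genome a) against the reference genome (b),
# derived from shred truth: used by the scaffolding reconstruction tests
scaffold_reference_pairs <- function(gene_track, shred_truth) {
  g <- gene_track[gene_track$category == "gene", ]
  out <- list()
  for (i in seq_len(nrow(g))) {
    f <- g[i, ]
    t <- shred_truth[shred_truth$chrom == f$chrom &
                       shred_truth$start <= f$start &
                       shred_truth$end >= f$end, ]
    if (!nrow(t)) next
    if (t$orientation == "+") {
      s <- f$start - t$start; e <- f$end - t$start; st <- f$strand
    } else {
      L <- t$end - t$start
      s <- L - (f$end - t$start); e <- L - (f$start - t$start)
      st <- ifelse(f$strand == "+", "-", "+")
    }
    out[[length(out) + 1]] <- tibble::tibble(
      gene_a = f$name, gene_b = f$name, chrom_a = t$scaffold, start_a = s,
      end_a = e, strand_a = st, chrom_b = f$chrom, start_b = f$start,
      end_b = f$end, strand_b = f$strand)
  }
  dplyr::bind_rows(out)
}
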