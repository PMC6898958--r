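# Anchor construction: maximal exact matches between two sequences, anchors
# from ortholog gene pairs, and clustering of raw matches onto ortholog
# pairs. Anchors are the atomic evidence for synteny; chaining them into
# blocks is the synteny module's job.

#' Find all maximal exact matches between two sequences
#'
#' Reports every maximal exact match of length >= `min_len` between two
#' nucleotide sequences (maximal: extendable in neither direction). `N`
#' never matches anything, including another `N`. Matches are found by
#' shared k-mer seeding (k = `min_len`) with per-diagonal run scanning.
#'
#' @param seq_a,seq_b Nucleotide strings (or `DNAString`s) over `{A,C,G,T,N}`.
#' @param min_len Minimum match length in bases (default 20).
#' @param both_strands Also search `seq_a` against the reverse complement of
#'   `seq_b`; such matches are reported with orientation `"-"` and
#'   plus-strand `seq_b` coordinates.
#' @param chrom_a,chrom_b Labels copied into the output.
#'
#' @return Tibble of raw matches: `chrom_a`, `start_a`, `end_a`, `chrom_b`,
#'   `start_b`, `end_b`, `orientation`, `length` (0-based half-open).
#' @export
find_exact_matches <- function(seq_a, seq_b, min_len = 20,
                               both_strands = FALSE,
                               chrom_a = "A", chrom_b = "B") {
  if (!is_scalar_integerish(min_len) || min_len < 1) {
    abort("`min_len` must be a positive integer")
  }
  a <- toupper(as.character(seq_a))
  b <- toupper(as.character(seq_b))
  if (grepl("[^ACGTN]", a) || grepl("[^ACGTN]", b)) {
    abort("sequences must be over {A,C,G,T,N}")
  }
  fwd <- .diagonal_matches(a, b, min_len)
  if (nrow(fwd)) fwd$orientation <- "+"
  out <- fwd
  if (both_strands) {
    rcb <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(b)))
    rev <- .diagonal_matches(a, rcb, min_len)
    if (nrow(rev)) {
      nb <- nchar(b)
      rev <- rev |>
        mutate(tmp = nb - .data$end_b, end_b = nb - .data$start_b,
               start_b = .data$tmp, orientation = "-") |>
        select(-"tmp")
      out <- bind_rows(out, rev)
    }
  }
  if (!nrow(out)) {
    return(tibble(chrom_a = character(), start_a = numeric(),
                  end_a = numeric(), chrom_b = character(),
                  start_b = numeric(), end_b = numeric(),
                  orientation = character(), length = numeric()))
  }
  out |>
    mutate(chrom_a = chrom_a, chrom_b = chrom_b,
           length = .data$end_a - .data$start_a) |>
    select("chrom_a", "start_a", "end_a", "chrom_b", "start_b", "end_b",
           "orientation", "length") |>
    arrange(.data$start_a, .data$start_b)
}

# all maximal runs of length >= k on diagonals that contain a shared k-mer;
# coordinates 0-based half-open on the forward orientations of both inputs
.diagonal_matches <- function(a, b, k) {
  empty <- tibble(start_a = numeric(), end_a = numeric(),
                  start_b = numeric(), end_b = numeric())
  na <- nchar(a); nb <- nchar(b)
  if (na < k || nb < k) return(empty)
  ka <- substring(a, 1:(na - k + 1), k:na)
  kb <- substring(b, 1:(nb - k + 1), k:nb)
  oka <- !grepl("N", ka, fixed = TRUE)
  okb <- !grepl("N", kb, fixed = TRUE)
  shared <- intersect(ka[oka], kb[okb])
  if (!length(shared)) return(empty)
  pa <- which(oka)[ka[oka] %in% shared]
  pb <- which(okb)[kb[okb] %in% shared]
  ia <- split(pa, ka[pa])
  ib <- split(pb, kb[pb])
  diags <- unique(unlist(purrr::map(shared, function(km) {
    as.vector(outer(ib[[km]], ia[[km]], `-`))
  })))
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  res <- purrr::map(diags, function(d) {
    # positions i in a matched with i + d in b
    lo <- max(1L, 1L - d); hi <- min(na, nb - d)
    if (hi - lo + 1 < k) return(NULL)
    ai <- av[lo:hi]; bi <- bv[(lo + d):(hi + d)]
    eq <- ai == bi & ai != "N" & bi != "N"
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    sel <- r$values & r$lengths >= k
    if (!any(sel)) return(NULL)
    s <- lo + starts[sel] - 1  # 1-based start in a
    l <- r$lengths[sel]
    tibble(start_a = s - 1, end_a = s - 1 + l,
           start_b = s + d - 1, end_b = s + d - 1 + l)
  })
  out <- list_rbind(discard(res, is.null))
  if (is.null(out) || !nrow(out)) return(empty)
  distinct(out)
}

#' Build anchors from an ortholog gene map
#'
#' One anchor per ortholog pair: orientation is the product of the two
#' members' strands, weight is the smaller of the two gene spans. Malformed
#' rows (unknown chromosome, inverted interval) are dropped with a warning,
#' or abort the run in strict mode.
#'
#' @param pairs Ortholog map tibble (see [emit_anchors()] for columns).
#' @param karyotype_a,karyotype_b Optional karyotypes used to validate
#'   chromosome names and interval bounds.
#' @param strict Abort on the first malformed row instead of warning.
#' @return An anchor tibble (`source = "ortholog"`).
#' @export
anchors_from_orthologs <- function(pairs, karyotype_a = NULL,
                                   karyotype_b = NULL, strict = FALSE) {
  .check_cols(pairs, c("gene_a", "gene_b", "chrom_a", "start_a", "end_a",
                       "strand_a", "chrom_b", "start_b", "end_b", "strand_b"),
              "`pairs`")
  bad <- pairs$start_a >= pairs$end_a | pairs$start_b >= pairs$end_b |
    pairs$start_a < 0 | pairs$start_b < 0
  chk <- function(kar, chrom, end) {
    if (is.null(kar)) return(rep(FALSE, length(chrom)))
    len <- kar$chromosomes$length[match(chrom, kar$chromosomes$chrom)]
    is.na(len) | end > len
  }
  bad <- bad | chk(karyotype_a, pairs$chrom_a, pairs$end_a) |
    chk(karyotype_b, pairs$chrom_b, pairs$end_b)
  if (any(bad)) {
    msg <- sprintf("%d malformed ortholog row(s)", sum(bad))
    if (strict) abort(paste0(msg, " (strict mode)"))
    warn(paste0(msg, " dropped"))
    pairs <- pairs[!bad, , drop = FALSE]
  }
  if (!nrow(pairs)) abort("no valid ortholog pairs remain")
  tibble(anchor_id = sprintf("a%06d", seq_len(nrow(pairs))),
         chrom_a = pairs$chrom_a, start_a = pairs$start_a,
         end_a = pairs$end_a, chrom_b = pairs$chrom_b,
         start_b = pairs$start_b, end_b = pairs$end_b,
         orientation = if_else(pairs$strand_a == pairs$strand_b, "+", "-"),
         weight = pmin(pairs$end_a - pairs$start_a,
                       pairs$end_b - pairs$start_b),
         source = "ortholog")
}

#' Cluster raw exact matches onto ortholog pairs
#'
#' Matches whose intervals on both genomes fall within `window` bases of an
#' ortholog pair's two gene intervals are grouped per pair and merged into a
#' single anchor spanning the group's extent; matches supporting no pair are
#' discarded. Output is deduplicated and independent of input match order.
#'
#' @param matches Raw match tibble from [find_exact_matches()].
#' @param pairs Ortholog map tibble.
#' @param window Assignment radius in bases around each gene interval.
#' @return An anchor tibble (`source = "merged"`).
#' @export
cluster_matches_to_anchors <- function(matches, pairs, window = 1e4) {
  .assert_scalar_num(window, "window", min = 0)
  if (!nrow(matches) || !nrow(pairs)) {
    return(tibble(anchor_id = character(), chrom_a = character(),
                  start_a = numeric(), end_a = numeric(),
                  chrom_b = character(), start_b = numeric(),
                  end_b = numeric(), orientation = character(),
                  weight = numeric(), source = character()))
  }
  matches <- arrange(matches, .data$chrom_a, .data$start_a, .data$start_b,
                     .data$orientation)
  anchors <- purrr::map(seq_len(nrow(pairs)), function(i) {
    p <- pairs[i, ]
    m <- matches |>
      filter(.data$chrom_a == p$chrom_a, .data$chrom_b == p$chrom_b,
             .data$start_a >= p$start_a - window,
             .data$end_a <= p$end_a + window,
             .data$start_b >= p$start_b - window,
             .data$end_b <= p$end_b + window)
    if (!nrow(m)) return(NULL)
    len_by_ori <- tapply(m$end_a - m$start_a, m$orientation, sum)
    ori <- names(len_by_ori)[which.max(len_by_ori)]
    tibble(chrom_a = p$chrom_a, start_a = min(m$start_a),
           end_a = max(m$end_a), chrom_b = p$chrom_b,
           start_b = min(m$start_b), end_b = max(m$end_b),
           orientation = ori,
           weight = max(m$end_a) - min(m$start_a), source = "merged")
  })
  out <- list_rbind(discard(anchors, is.null))
  if (is.null(out) || !nrow(out)) {
    return(cluster_matches_to_anchors(matches[0, ], pairs[0, ], window))
  }
  out |>
    distinct() |>
    arrange(.data$chrom_a, .data$start_a, .data$chrom_b, .data$start_b) |>
    mutate(anchor_id = sprintf("a%06d", row_number())) |>
    select("anchor_id", dplyr::everything())
}
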