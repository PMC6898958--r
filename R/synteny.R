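# Chaining anchors into large-scale homologous synteny blocks (HSBs).
#
# Chains are score-maximal weighted collinear subsequences of anchors per
# (chrom_a, chrom_b, orientation) stratum, found by dynamic programming and
# extracted greedily (best chain first, anchors removed, repeat). Small
# internal order/orientation violations — micro-rearrangements — are
# tolerated inside a block: a run of foreign anchors interrupting a block
# only splits it when the run's extent exceeds `micro_tolerance`.

# Collinearity predicate shared by chaining and documented for the oracle:
# anchor j may precede i within a stratum iff
#   start_a[j] < start_a[i],
#   start_b ordered per block orientation (strictly increasing for "+",
#   strictly decreasing for "-"),
#   gap on genome A (start_a[i] - end_a[j]) <= max_gap, and
#   gap on genome B (orientation-dependent)  <= max_gap.
# Negative gaps (overlapping anchors) are allowed.

.chain_ok <- function(anc, j, i, orientation, max_gap) {
  if (!(anc$start_a[j] < anc$start_a[i])) return(FALSE)
  if (anc$start_a[i] - anc$end_a[j] > max_gap) return(FALSE)
  if (orientation == "+") {
    anc$start_b[j] < anc$start_b[i] &&
      anc$start_b[i] - anc$end_b[j] <= max_gap
  } else {
    anc$start_b[i] < anc$start_b[j] &&
      anc$start_b[j] - anc$end_b[i] <= max_gap
  }
}

# best-score chain in one stratum (anchors pre-sorted by start_a, start_b);
# returns indices of the winning chain
.best_chain <- function(anc, orientation, max_gap) {
  n <- nrow(anc)
  dp <- anc$weight
  parent <- rep(NA_integer_, n)
  if (n > 1) {
    for (i in 2:n) {
      for (j in 1:(i - 1)) {
        if (.chain_ok(anc, j, i, orientation, max_gap)) {
          cand <- dp[j] + anc$weight[i]
          if (cand > dp[i]) {
            dp[i] <- cand
            parent[i] <- j
          }
        }
      }
    }
  }
  # ties: higher score, then longer span on genome A, then first index
  best <- which(dp == max(dp))
  if (length(best) > 1) {
    spans <- purrr::map_dbl(best, function(i) {
      idx <- i
      while (!is.na(parent[idx[1]])) idx <- c(parent[idx[1]], idx)
      max(anc$end_a[idx]) - min(anc$start_a[idx])
    })
    best <- best[order(-spans, best)][1]
  } else best <- best[1]
  idx <- best
  while (!is.na(parent[idx[1]])) idx <- c(parent[idx[1]], idx)
  idx
}

#' Chain anchors into homologous synteny blocks
#'
#' Builds score-maximal collinear chains of anchors per chromosome pair and
#' orientation, tolerating internal micro-rearrangements up to
#' `micro_tolerance` bases, and returns them as HSBs with extents on both
#' genomes. Each anchor belongs to at most one HSB; conflicts go to the
#' higher-scoring chain. Blocks overlapping on a genome are trimmed at the
#' midpoint of the overlap so that downstream breakpoint detection sees
#' non-overlapping flanks.
#'
#' @param anchors Anchor tibble (see [emit_anchors()]).
#' @param max_gap Maximum gap in bases between consecutive chain anchors on
#'   either genome (default 2 Mb).
#' @param min_anchors Minimum anchors per block (default 3).
#' @param min_span Minimum block span in bases on both genomes (default
#'   1 Mb) — the operational meaning of "large-scale".
#' @param micro_tolerance Maximal extent in bases of an internal run of
#'   order/orientation-violating anchors absorbed inside a block rather
#'   than splitting it (default 200 kb).
#'
#' @return An HSB tibble of class `hsb_tbl`: `hsb_id`, coordinates on both
#'   genomes, `orientation`, `n_anchors`, `span_a`, `span_b`, `score`,
#'   `anchor_ids` (list column).
#' @export
chain_anchors <- function(anchors, max_gap = 2e6, min_anchors = 3,
                          min_span = 1e6, micro_tolerance = 2e5) {
  .assert_scalar_num(max_gap, "max_gap", min = 0)
  .assert_scalar_num(min_anchors, "min_anchors", min = 1)
  .assert_scalar_num(min_span, "min_span", min = 0)
  .assert_scalar_num(micro_tolerance, "micro_tolerance", min = 0)
  empty <- structure(
    tibble(hsb_id = character(), chrom_a = character(), start_a = numeric(),
           end_a = numeric(), chrom_b = character(), start_b = numeric(),
           end_b = numeric(), orientation = character(),
           n_anchors = integer(), span_a = numeric(), span_b = numeric(),
           score = numeric(), anchor_ids = list()),
    class = c("hsb_tbl", class(tibble())))
  if (is.null(anchors) || !nrow(anchors)) return(empty)
  .check_cols(anchors, c("anchor_id", "chrom_a", "start_a", "end_a",
                         "chrom_b", "start_b", "end_b", "orientation",
                         "weight"), "`anchors`")

  anchors <- arrange(anchors, .data$chrom_a, .data$start_a, .data$start_b,
                     .data$orientation, .data$anchor_id)

  chains <- list()
  strata <- anchors |>
    group_by(.data$chrom_a, .data$chrom_b, .data$orientation) |>
    dplyr::group_split()
  for (st in strata) {
    ori <- st$orientation[1]
    pool <- st
    while (nrow(pool)) {
      idx <- .best_chain(pool, ori, max_gap)
      chains[[length(chains) + 1]] <- pool[idx, ]
      pool <- pool[-idx, , drop = FALSE]
    }
  }

  blocks <- purrr::map(chains, function(ch) {
    tibble(chrom_a = ch$chrom_a[1], start_a = min(ch$start_a),
           end_a = max(ch$end_a), chrom_b = ch$chrom_b[1],
           start_b = min(ch$start_b), end_b = max(ch$end_b),
           orientation = ch$orientation[1], n_anchors = nrow(ch),
           score = sum(ch$weight), anchor_ids = list(ch$anchor_id),
           members = list(ch))
  }) |> list_rbind()

  # split blocks at internal foreign runs wider than micro_tolerance
  blocks <- .split_at_macro_violations(blocks, anchors, micro_tolerance)

  blocks <- blocks |>
    mutate(span_a = .data$end_a - .data$start_a,
           span_b = .data$end_b - .data$start_b) |>
    filter(.data$n_anchors >= min_anchors,
           .data$span_a >= min_span, .data$span_b >= min_span)
  if (!nrow(blocks)) return(empty)

  blocks <- .trim_overlaps(blocks, "a")
  blocks <- .trim_overlaps(blocks, "b")

  out <- blocks |>
    arrange(.data$chrom_a, .data$start_a) |>
    mutate(hsb_id = sprintf("hsb_%03d", row_number()),
           span_a = .data$end_a - .data$start_a,
           span_b = .data$end_b - .data$start_b) |>
    select("hsb_id", "chrom_a", "start_a", "end_a", "chrom_b", "start_b",
           "end_b", "orientation", "n_anchors", "span_a", "span_b",
           "score", "anchor_ids") |>
    structure(class = c("hsb_tbl", class(tibble())))
  # raw chain scores from the extraction stage (before micro-splitting and
  # filtering): the quantity the chaining optimality guarantee refers to
  attr(out, "chain_scores") <- purrr::map_dbl(chains, ~sum(.x$weight))
  out
}

# a block containing a run of foreign anchors (anchors of other chains)
# wider than micro_tolerance on genome A is split between the member
# anchors flanking that run
.split_at_macro_violations <- function(blocks, anchors, micro_tolerance) {
  out <- list()
  for (i in seq_len(nrow(blocks))) {
    blk <- blocks[i, ]
    mem <- blk$members[[1]] |> arrange(.data$start_a)
    foreign <- anchors |>
      filter(.data$chrom_a == blk$chrom_a,
             !.data$anchor_id %in% mem$anchor_id,
             .data$start_a >= blk$start_a, .data$end_a <= blk$end_a)
    if (!nrow(foreign) || nrow(mem) < 2) {
      out[[length(out) + 1]] <- blk
      next
    }
    # bucket foreign anchors by the member gap they fall into
    gap_idx <- findInterval(foreign$start_a, mem$start_a)
    splits <- integer(0)
    for (g in unique(gap_idx)) {
      if (g < 1 || g >= nrow(mem)) next
      run <- foreign[gap_idx == g, ]
      if (max(run$end_a) - min(run$start_a) > micro_tolerance) {
        splits <- c(splits, g)
      }
    }
    if (!length(splits)) {
      out[[length(out) + 1]] <- blk
      next
    }
    bounds <- c(0, sort(splits), nrow(mem))
    for (k in seq_len(length(bounds) - 1)) {
      part <- mem[(bounds[k] + 1):bounds[k + 1], ]
      out[[length(out) + 1]] <- tibble(
        chrom_a = part$chrom_a[1], start_a = min(part$start_a),
        end_a = max(part$end_a), chrom_b = part$chrom_b[1],
        start_b = min(part$start_b), end_b = max(part$end_b),
        orientation = part$orientation[1], n_anchors = nrow(part),
        score = sum(part$weight), anchor_ids = list(part$anchor_id),
        members = list(part))
    }
  }
  list_rbind(out)
}

# overlapping block ends on one genome trimmed at the midpoint of the overlap
.trim_overlaps <- function(blocks, genome = c("a", "b")) {
  genome <- match.arg(genome)
  ch <- paste0("chrom_", genome)
  s <- paste0("start_", genome)
  e <- paste0("end_", genome)
  blocks <- blocks[order(blocks[[ch]], blocks[[s]], blocks[[e]]), ]
  for (i in seq_len(nrow(blocks) - 1)) {
    j <- i + 1
    if (blocks[[ch]][i] != blocks[[ch]][j]) next
    if (blocks[[e]][i] > blocks[[s]][j]) {
      mid <- floor((blocks[[e]][i] + blocks[[s]][j]) / 2)
      blocks[[e]][i] <- mid
      blocks[[s]][j] <- mid
    }
  }
  blocks[blocks[[e]] > blocks[[s]], , drop = FALSE]
}

#' Summarise an HSB set for one pairwise comparison
#'
#' @param hsbs HSB tibble from [chain_anchors()].
#' @param karyotype_a,karyotype_b Optional karyotypes; when given, coverage
#'   fractions (span sum / genome length) are reported.
#' @return One-row tibble: `n_hsbs`, `total_span_a`, `total_span_b`,
#'   `coverage_a`, `coverage_b`.
#' @export
hsb_table <- function(hsbs, karyotype_a = NULL, karyotype_b = NULL) {
  cov <- function(total, kar) {
    if (is.null(kar)) NA_real_ else total / sum(kar$chromosomes$length)
  }
  ta <- sum(hsbs$span_a %||% numeric(0))
  tb <- sum(hsbs$span_b %||% numeric(0))
  tibble(n_hsbs = nrow(hsbs), total_span_a = ta, total_span_b = tb,
         coverage_a = if (nrow(hsbs)) cov(ta, karyotype_a) else
           if (is.null(karyotype_a)) NA_real_ else 0,
         coverage_b = if (nrow(hsbs)) cov(tb, karyotype_b) else
           if (is.null(karyotype_b)) NA_real_ else 0)
}
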