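# Evolutionary breakpoint regions (EBRs): the interval on one genome
# between two adjacent large-scale HSBs, demarcated exactly by the HSB end
# coordinates on each side. Interchromosomal EBRs (different partner
# chromosomes on the two flanks) are the footprint of chromosome fission.

.ebr_cols <- function() {
  tibble(ebr_id = character(), genome_id = character(), chrom = character(),
         start = numeric(), end = numeric(), flank_left = character(),
         flank_right = character(), partner_left = character(),
         partner_right = character(), kind = character(), sources = list())
}

.target_cols <- function(target = c("a", "b")) {
  target <- match.arg(target)
  other <- if (target == "a") "b" else "a"
  list(chrom = paste0("chrom_", target), start = paste0("start_", target),
       end = paste0("end_", target), partner = paste0("chrom_", other))
}

.check_no_overlap <- function(hsbs, cols) {
  ord <- order(hsbs[[cols$chrom]], hsbs[[cols$start]])
  h <- hsbs[ord, ]
  same <- h[[cols$chrom]][-1] == h[[cols$chrom]][-nrow(h)]
  over <- h[[cols$start]][-1] < h[[cols$end]][-nrow(h)] & same
  if (any(over)) {
    i <- which(over)[1]
    abort(sprintf("HSBs overlap on the target genome: %s and %s",
                  h$hsb_id[i], h$hsb_id[i + 1]))
  }
  h
}

#' Detect evolutionary breakpoint regions between adjacent HSBs
#'
#' Sorts HSBs along each target-genome chromosome and emits one EBR per gap
#' between consecutive blocks. Chromosome-terminal gaps are not EBRs (the
#' definition requires an HSB on each side). An EBR is interchromosomal
#' when its two flanking blocks map to different partner chromosomes —
#' the signature of a fission. Abutting blocks with different partners emit
#' a 1-bp EBR at the junction so fission evidence is never dropped.
#'
#' @param hsbs HSB tibble from [chain_anchors()].
#' @param target `"a"` or `"b"`: the genome whose chromosomes carry the
#'   EBRs.
#' @param fission_only Return only interchromosomal EBRs.
#' @param genome_id Label stored in the output (defaults to the target
#'   letter).
#' @param comparison Label recorded in the `sources` column, e.g.
#'   `"panda_vs_dog"`.
#' @return An EBR tibble of class `ebr_tbl`.
#' @export
detect_ebrs <- function(hsbs, target = c("a", "b"), fission_only = FALSE,
                        genome_id = NULL, comparison = "A_vs_B") {
  target <- match.arg(target)
  cols <- .target_cols(target)
  gid <- genome_id %||% toupper(target)
  if (!nrow(hsbs)) return(structure(.ebr_cols(),
                                    class = c("ebr_tbl", class(tibble()))))
  h <- .check_no_overlap(hsbs, cols)

  out <- h |>
    mutate(.chrom = .data[[cols$chrom]], .start = .data[[cols$start]],
           .end = .data[[cols$end]], .partner = .data[[cols$partner]]) |>
    group_by(.data$.chrom) |>
    arrange(.data$.start, .by_group = TRUE) |>
    summarise(ebr = list({
      n <- dplyr::n()
      if (n < 2) .ebr_cols() else {
        gs <- .end[-n]; ge <- .start[-1]
        pl <- .partner[-n]; pr <- .partner[-1]
        keep <- ge > gs | (ge == gs & pl != pr)
        tibble(chrom = .chrom[1],
               start = gs, end = if_else(ge > gs, ge, gs + 1),
               flank_left = hsb_id[-n], flank_right = hsb_id[-1],
               partner_left = pl, partner_right = pr,
               kind = if_else(pl != pr, "interchromosomal",
                              "intrachromosomal"))[keep, ]
      }
    }), .groups = "drop") |>
    pull(.data$ebr) |>
    list_rbind()

  if (is.null(out) || !nrow(out)) {
    return(structure(.ebr_cols(), class = c("ebr_tbl", class(tibble()))))
  }
  if (fission_only) out <- filter(out, .data$kind == "interchromosomal")
  out <- out |>
    arrange(.data$chrom, .data$start) |>
    mutate(genome_id = gid,
           ebr_id = sprintf("%s_ebr%03d", comparison, row_number()),
           sources = purrr::map(row_number(), ~comparison)) |>
    select("ebr_id", "genome_id", "chrom", "start", "end", "flank_left",
           "flank_right", "partner_left", "partner_right", "kind", "sources")
  structure(out, class = c("ebr_tbl", class(tibble())))
}

#' Count interchromosomal fission events along the target genome
#'
#' The number of adjacent HSB pairs whose partner chromosomes differ,
#' summed over target chromosomes; equivalently, per chromosome, the number
#' of maximal same-partner runs minus one.
#'
#' @inheritParams detect_ebrs
#' @return Integer count of fission events.
#' @export
count_fission_events <- function(hsbs, target = c("a", "b")) {
  target <- match.arg(target)
  if (!nrow(hsbs)) return(0L)
  cols <- .target_cols(target)
  h <- .check_no_overlap(hsbs, cols)
  h |>
    group_by(chrom = .data[[cols$chrom]]) |>
    arrange(.data[[cols$start]], .by_group = TRUE) |>
    summarise(n_trans = sum(.data[[cols$partner]] !=
                              lag(.data[[cols$partner]]), na.rm = TRUE),
              .groups = "drop") |>
    pull(.data$n_trans) |>
    sum() |>
    as.integer()
}

#' Merge two EBR sets on the same genome
#'
#' EBRs sharing at least one base are merged into a single record spanning
#' the union interval, with sources unioned; transitive overlaps collapse
#' into one record. The overlap pair count is the number of merged groups
#' containing members of both input sets (members identical by `ebr_id`
#' count as one set, so merging a set with itself reports zero cross-set
#' pairs).
#'
#' @param set_1,set_2 EBR tibbles on the same genome.
#' @return List with `ebrs` (merged EBR tibble) and `overlap_pair_count`.
#' @export
merge_ebr_sets <- function(set_1, set_2) {
  for (s in list(set_1, set_2)) {
    .check_cols(s, c("ebr_id", "genome_id", "chrom", "start", "end"),
                "EBR set")
  }
  gids <- unique(c(set_1$genome_id, set_2$genome_id))
  if (length(gids) > 1) {
    abort(sprintf("EBR sets are on different genomes: %s",
                  paste(gids, collapse = " vs ")))
  }
  all <- bind_rows(mutate(set_1, .set = 1L), mutate(set_2, .set = 2L))
  if (!nrow(all)) {
    return(list(ebrs = structure(.ebr_cols(),
                                 class = c("ebr_tbl", class(tibble()))),
                overlap_pair_count = 0L))
  }
  merged <- list()
  n_cross <- 0L
  for (cn in unique(all$chrom)) {
    x <- all |> filter(.data$chrom == cn)
    ir <- .ir(x$start, x$end)
    red <- IRanges::reduce(ir)
    grp <- S4Vectors::subjectHits(IRanges::findOverlaps(ir, red))
    for (g in seq_along(red)) {
      mem <- x[grp == g, ]
      col_or <- function(nm) {
        if (nm %in% names(mem)) mem[[nm]] else NA_character_
      }
      src <- sort(unique(unlist(if ("sources" %in% names(mem)) mem$sources
                                else mem$ebr_id)))
      cross <- length(unique(mem$ebr_id[mem$.set == 1L])) > 0 &&
        length(unique(mem$ebr_id[mem$.set == 2L])) > 0 &&
        length(setdiff(mem$ebr_id[mem$.set == 2L],
                       mem$ebr_id[mem$.set == 1L])) > 0
      if (cross) n_cross <- n_cross + 1L
      uq <- function(v) if (length(unique(v)) == 1) v[1] else NA_character_
      merged[[length(merged) + 1]] <- tibble(
        genome_id = gids, chrom = cn,
        start = IRanges::start(red)[g] - 1, end = IRanges::end(red)[g],
        flank_left = uq(col_or("flank_left")),
        flank_right = uq(col_or("flank_right")),
        partner_left = uq(col_or("partner_left")),
        partner_right = uq(col_or("partner_right")),
        kind = if (any(col_or("kind") == "interchromosomal", na.rm = TRUE))
          "interchromosomal" else uq(col_or("kind")),
        sources = list(src))
    }
  }
  out <- list_rbind(merged) |>
    arrange(.data$chrom, .data$start) |>
    mutate(ebr_id = sprintf("m_ebr%03d", row_number())) |>
    select("ebr_id", dplyr::everything())
  list(ebrs = structure(out, class = c("ebr_tbl", class(tibble()))),
       overlap_pair_count = n_cross)
}

#' Summarise an EBR set
#'
#' @param ebrs An EBR tibble.
#' @return List with `stats` (one-row tibble: `n`, `total_span`,
#'   `min_length`, `max_length`, `mean_length`) and `per_chromosome`
#'   (tibble of per-chromosome counts).
#' @export
ebr_summary <- function(ebrs) {
  if (!nrow(ebrs)) {
    return(list(stats = tibble(n = 0L, total_span = 0, min_length = 0,
                               max_length = 0, mean_length = 0),
                per_chromosome = tibble(chrom = character(), n = integer())))
  }
  len <- ebrs$end - ebrs$start
  list(stats = tibble(n = nrow(ebrs), total_span = sum(len),
                      min_length = min(len), max_length = max(len),
                      mean_length = mean(len)),
       per_chromosome = count(ebrs, .data$chrom, name = "n"))
}
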