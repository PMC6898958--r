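# Reference-assisted chromosome construction: assign scaffolds to
# chromosomes from flow-sorted-library coverage, resolve mixed libraries
# with synteny against a related reference genome, order and orient the
# scaffolds along each chromosome, and emit the layout as AGP v2.1 plus an
# ordered FASTA.

#' Assign scaffolds to sorted-chromosome libraries by coverage
#'
#' Each coverage column is normalized by its library-wide median depth
#' (libraries are sequenced to very different depths, so raw columns are
#' not comparable). A scaffold is assigned to the library with the highest
#' normalized signal iff best / second-best >= `min_ratio`; otherwise it
#' lands in the ambiguous set. Scaling a column by a constant does not
#' change assignments.
#'
#' @param matrix_tbl Tibble: `scaffold` column plus one numeric column per
#'   library (mean read depth).
#' @param min_ratio Required fold between best and second-best signal
#'   (> 1; default 3).
#' @return Tibble: `scaffold`, `library` (NA when ambiguous), `confidence`
#'   (best / second-best), `ambiguous`.
#' @export
assign_by_coverage <- function(matrix_tbl, min_ratio = 3) {
  .check_cols(matrix_tbl, "scaffold", "coverage matrix")
  if (min_ratio <= 1) abort("`min_ratio` must be > 1")
  libs <- setdiff(names(matrix_tbl), "scaffold")
  if (!length(libs) || !nrow(matrix_tbl)) abort("coverage matrix is empty")
  m <- as.matrix(matrix_tbl[libs])
  if (any(m < 0)) abort("depths must be >= 0")
  med <- apply(m, 2, median)
  med[med <= 0] <- 1
  norm <- sweep(m, 2, med, "/")
  res <- purrr::map(seq_len(nrow(norm)), function(i) {
    v <- norm[i, ]
    if (all(v == 0)) {
      return(tibble(scaffold = matrix_tbl$scaffold[i],
                    library = NA_character_, confidence = NA_real_,
                    ambiguous = TRUE))
    }
    ord <- order(v, decreasing = TRUE)
    best <- v[ord[1]]
    second <- if (length(v) > 1) v[ord[2]] else 0
    conf <- if (second > 0) best / second else Inf
    amb <- conf < min_ratio
    tibble(scaffold = matrix_tbl$scaffold[i],
           library = if (amb) NA_character_ else libs[ord[1]],
           confidence = conf, ambiguous = amb)
  }) |> list_rbind()
  n_zero <- sum(is.na(res$confidence))
  if (n_zero) warn(sprintf("%d scaffold(s) with all-zero coverage", n_zero))
  res
}

#' Resolve mixed-library or ambiguous scaffolds with reference synteny
#'
#' A scaffold from a mixed library (one library containing several
#' chromosomes) is assigned to the member chromosome whose corresponding
#' reference chromosome carries the majority of the scaffold's aligned HSB
#' span; it stays unresolved below the majority threshold or without any
#' reference HSB.
#'
#' @param assignments Output of [assign_by_coverage()] (the `library`
#'   column may name a mixed library such as `"chr10+chr11"`).
#' @param hsbs HSB tibble of scaffolds (genome A) against the reference
#'   genome (genome B).
#' @param correspondence Tibble with columns `ref_chrom`, `target_chrom`:
#'   the cross-species chromosome homology map (an input, not inferred).
#' @param majority Minimum fraction of aligned span required (default 0.6).
#' @return `assignments` with a `chromosome` column: the resolved target
#'   chromosome (NA when unresolved) and an updated `ambiguous` flag.
#' @export
resolve_with_reference <- function(assignments, hsbs, correspondence,
                                   majority = 0.6) {
  .check_cols(correspondence, c("ref_chrom", "target_chrom"),
              "`correspondence`")
  span_by_target <- hsbs |>
    left_join(correspondence, by = c(chrom_b = "ref_chrom")) |>
    filter(!is.na(.data$target_chrom)) |>
    group_by(scaffold = .data$chrom_a, .data$target_chrom) |>
    summarise(span = sum(.data$span_a), .groups = "drop")

  resolve_one <- function(scaffold, members) {
    sp <- span_by_target |>
      filter(.data$scaffold == !!scaffold, .data$target_chrom %in% members)
    if (!nrow(sp)) return(NA_character_)
    tot <- sum(sp$span)
    best <- sp |> arrange(dplyr::desc(.data$span)) |> slice(1)
    if (best$span / tot >= majority) best$target_chrom else NA_character_
  }

  assignments |>
    mutate(chromosome = purrr::map_chr(row_number(), function(i) {
      lib <- assignments$library[i]
      if (is.na(lib)) {
        # fully ambiguous: allow any target chromosome
        return(resolve_one(assignments$scaffold[i],
                           unique(correspondence$target_chrom)))
      }
      members <- strsplit(lib, "+", fixed = TRUE)[[1]]
      if (length(members) == 1) return(members)
      resolve_one(assignments$scaffold[i], members)
    })) |>
    mutate(ambiguous = is.na(.data$chromosome))
}

#' Order and orient scaffolds along chromosomes using reference synteny
#'
#' Within each chromosome, scaffolds are ordered by the span-weighted
#' median reference coordinate of their HSBs; orientation is the majority
#' HSB orientation when at least `orient_majority` of the aligned span
#' agrees, else `"unknown"` (the honest state for scaffolds whose strand
#' the evidence cannot settle). Ranks are dense from 1.
#'
#' @param assignments Tibble with `scaffold` and `chromosome` columns
#'   (e.g. from [resolve_with_reference()]); unassigned scaffolds are
#'   skipped.
#' @param hsbs HSB tibble of scaffolds (genome A) vs the reference
#'   (genome B).
#' @param orient_majority Span fraction required to call an orientation.
#' @return Tibble of placements: `scaffold`, `chromosome`, `rank`,
#'   `orientation`, `evidence`, `confidence`.
#' @export
order_by_reference <- function(assignments, hsbs, orient_majority = 0.7) {
  placed <- assignments |> filter(!is.na(.data$chromosome))
  if (!nrow(placed)) abort("no scaffolds assigned to chromosomes")
  placed$evidence <- if ("library" %in% names(placed)) {
    if_else(is.na(placed$library), "synteny", "both")
  } else "synteny"
  per_scaffold <- hsbs |>
    filter(.data$chrom_a %in% placed$scaffold) |>
    group_by(scaffold = .data$chrom_a) |>
    summarise(
      ref_pos = {
        mids <- (.data$start_b + .data$end_b) / 2
        w <- .data$span_a
        # span-weighted median of HSB reference midpoints
        o <- order(mids)
        cw <- cumsum(w[o]) / sum(w)
        mids[o][which(cw >= 0.5)[1]]
      },
      plus_span = sum(.data$span_a[.data$orientation == "+"]),
      total_span = sum(.data$span_a),
      .groups = "drop")
  missing <- setdiff(placed$scaffold, per_scaffold$scaffold)
  if (length(missing)) {
    abort(sprintf("scaffold(s) without reference HSBs: %s",
                  paste(head(missing, 3), collapse = ", ")))
  }
  placed |>
    inner_join(per_scaffold, by = "scaffold") |>
    group_by(.data$chromosome) |>
    arrange(.data$ref_pos, .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    ungroup() |>
    mutate(
      frac_plus = .data$plus_span / .data$total_span,
      orientation = dplyr::case_when(
        .data$frac_plus >= orient_majority ~ "+",
        .data$frac_plus <= 1 - orient_majority ~ "-",
        TRUE ~ "unknown")) |>
    select("scaffold", "chromosome", "rank", "orientation", "evidence",
           dplyr::any_of("confidence"))
}

#' Materialize a chromosome layout as AGP v2.1 and ordered FASTA
#'
#' Builds an AGP v2.1 table (1-based inclusive coordinates, alternating
#' component and gap lines) from scaffold placements, and, when the
#' scaffold karyotype carries sequences, the corresponding chromosome
#' sequences with minus-strand scaffolds reverse-complemented and gaps
#' filled with `N`.
#'
#' @param placements Tibble from [order_by_reference()].
#' @param scaffolds [karyotype()] of the scaffolds (sequences optional).
#' @param gap_size Bases of `N` between consecutive scaffolds (default 100).
#' @param genome_id Genome id of the resulting chromosome-level karyotype.
#' @return List: `agp` (tibble in AGP column order), `karyotype`
#'   (chromosome-level, with sequences when available).
#' @export
emit_layout <- function(placements, scaffolds, gap_size = 100,
                        genome_id = "assembled") {
  .check_cols(placements, c("scaffold", "chromosome", "rank", "orientation"),
              "`placements`")
  if (anyDuplicated(placements$scaffold)) {
    abort("duplicate scaffold placement")
  }
  sc_len <- setNames(scaffolds$chromosomes$length,
                     scaffolds$chromosomes$chrom)
  agp <- list()
  seqs <- list()
  for (cn in unique(placements$chromosome)) {
    p <- placements |> filter(.data$chromosome == cn) |> arrange(.data$rank)
    if (!all(p$rank == seq_len(nrow(p)))) {
      abort(sprintf("ranks on %s are not dense from 1", cn))
    }
    pos <- 0
    part <- 0L
    pieces <- character(0)
    for (i in seq_len(nrow(p))) {
      if (i > 1 && gap_size > 0) {
        part <- part + 1L
        agp[[length(agp) + 1]] <- tibble(
          object = cn, object_beg = pos + 1, object_end = pos + gap_size,
          part_number = part, component_type = "N",
          component_id = as.character(gap_size), component_beg = "scaffold",
          component_end = "yes", orientation = "align_genus")
        pos <- pos + gap_size
        pieces <- c(pieces, strrep("N", gap_size))
      }
      sc <- p$scaffold[i]
      len <- unname(sc_len[sc])
      if (is.na(len)) abort(sprintf("unknown scaffold '%s'", sc))
      part <- part + 1L
      ori <- p$orientation[i]
      agp[[length(agp) + 1]] <- tibble(
        object = cn, object_beg = pos + 1, object_end = pos + len,
        part_number = part, component_type = "W", component_id = sc,
        component_beg = "1", component_end = as.character(len),
        orientation = if (ori == "unknown") "?" else ori)
      pos <- pos + len
      if (!is.null(scaffolds$seqs)) {
        s <- scaffolds$seqs[[sc]]
        if (ori == "-") s <- Biostrings::reverseComplement(s)
        pieces <- c(pieces, as.character(s))
      }
    }
    if (!is.null(scaffolds$seqs)) seqs[[cn]] <- paste(pieces, collapse = "")
  }
  agp <- list_rbind(agp)
  chroms <- agp |>
    group_by(chrom = .data$object) |>
    summarise(length = max(.data$object_end), .groups = "drop")
  kar <- karyotype(genome_id, chroms,
                   if (length(seqs)) Biostrings::DNAStringSet(unlist(seqs))
                   else NULL)
  list(agp = agp, karyotype = kar)
}

#' Write / read an AGP v2.1 file
#'
#' @param agp AGP tibble from [emit_layout()].
#' @param path File path.
#' @return `read_agp` returns the AGP tibble; `write_agp` returns the path
#'   invisibly.
#' @export
write_agp <- function(agp, path) {
  hdr <- "##agp-version\t2.1"
  lines <- c(hdr, purrr::map_chr(seq_len(nrow(agp)), function(i) {
    paste(unlist(lapply(agp[i, ], as.character)), collapse = "\t")
  }))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_agp
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 9)
  if (length(bad)) abort(sprintf("malformed AGP line %d", bad[1]))
  m <- do.call(rbind, parts)
  tibble(object = m[, 1], object_beg = as.numeric(m[, 2]),
         object_end = as.numeric(m[, 3]), part_number = as.integer(m[, 4]),
         component_type = m[, 5], component_id = m[, 6],
         component_beg = m[, 7], component_end = m[, 8],
         orientation = m[, 9])
}

#' Recover scaffold placements from an AGP table
#'
#' @param agp AGP tibble (component lines are used).
#' @return Placement tibble (`scaffold`, `chromosome`, `rank`,
#'   `orientation`).
#' @export
agp_to_placements <- function(agp) {
  agp |>
    filter(.data$component_type == "W") |>
    group_by(chromosome = .data$object) |>
    arrange(.data$object_beg, .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    ungroup() |>
    transmute(scaffold = .data$component_id, .data$chromosome, .data$rank,
              orientation = if_else(.data$orientation == "?", "unknown",
                                    .data$orientation))
}
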