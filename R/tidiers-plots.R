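# broom-style tidiers and ggplot2 visualisations for result objects.

#' Tidy a pipeline run into a per-comparison tibble
#'
#' @param x A `breakscape_run` from [run_pipeline()].
#' @param ... Unused.
#' @return Tibble: one row per pairwise comparison with anchor, HSB, EBR
#'   and fission counts.
#' @export
tidy.breakscape_run <- function(x, ...) {
  purrr::map(x$comparisons, function(cmp) {
    tibble(comparison = cmp$label, target = cmp$target, other = cmp$other,
           n_anchors = cmp$n_anchors, n_hsbs = nrow(cmp$hsbs),
           n_ebrs = nrow(cmp$ebrs),
           n_interchromosomal = sum(cmp$ebrs$kind == "interchromosomal"),
           fission_events = cmp$fission_events,
           coverage_target = cmp$hsb_summary$coverage_a)
  }) |> list_rbind()
}

#' One-row summary of a pipeline run
#'
#' @inheritParams tidy.breakscape_run
#' @return One-row tibble with totals across comparisons and per-genome
#'   merged EBR counts.
#' @export
glance.breakscape_run <- function(x, ...) {
  td <- tidy(x)
  merged <- purrr::map_int(x$merged_ebrs, ~nrow(.x$ebrs))
  out <- tibble(version = x$version, config_hash = x$config_hash,
                n_genomes = length(x$genomes),
                n_comparisons = x$n_comparisons,
                total_anchors = sum(td$n_anchors),
                total_hsbs = sum(td$n_hsbs), total_ebrs = sum(td$n_ebrs),
                total_fissions = sum(td$fission_events))
  for (g in names(merged)) out[[paste0("union_ebrs_", g)]] <- merged[[g]]
  out
}

#' Synteny dot/segment plot of an HSB set
#'
#' Each block is drawn as a segment from its genome-A extent to its
#' genome-B extent, faceted by chromosome pair and coloured by orientation.
#'
#' @param object An `hsb_tbl` from [chain_anchors()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hsb_tbl <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(pair = paste(.data$chrom_a, "vs", .data$chrom_b),
           y0 = if_else(.data$orientation == "+", .data$start_b, .data$end_b),
           y1 = if_else(.data$orientation == "+", .data$end_b, .data$start_b))
  ggplot(df, aes(x = .data$start_a / 1e6, xend = .data$end_a / 1e6,
                 y = .data$y0 / 1e6, yend = .data$y1 / 1e6,
                 colour = .data$orientation)) +
    geom_segment(linewidth = 1) +
    facet_wrap(~pair, scales = "free") +
    scale_colour_manual(values = c("+" = "#2166ac", "-" = "#b2182b")) +
    labs(x = "genome A position (Mb)", y = "genome B position (Mb)",
         colour = "orientation") +
    theme_bw()
}

#' @rdname autoplot.hsb_tbl
#' @param hsbs An `hsb_tbl`.
#' @export
plot_synteny <- function(hsbs, ...) autoplot.hsb_tbl(hsbs, ...)

#' EBR positions along chromosomes
#'
#' @param object An `ebr_tbl` from [detect_ebrs()] or [merge_ebr_sets()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ebr_tbl <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = (.data$start + .data$end) / 2e6, y = .data$chrom,
                 colour = .data$kind)) +
    geom_point(shape = 124, size = 5) +
    labs(x = "position (Mb)", y = NULL, colour = "EBR kind") +
    theme_bw()
}

#' Feature-comparison significance plot
#'
#' Bars of -log10 p for each feature and scope from
#' [compare_ebr_features()], with the 0.05 reference line.
#'
#' @param object An `ebr_feature_stats` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ebr_feature_stats <- function(object, ...) {
  df <- as_tibble(object) |> filter(!is.na(.data$p_value))
  ggplot(df, aes(x = .data$feature, y = -log10(.data$p_value),
                 fill = .data$direction)) +
    geom_col(position = "dodge") +
    geom_hline(yintercept = -log10(0.05), linetype = 2) +
    facet_wrap(~scope) +
    labs(x = NULL, y = expression(-log[10](p)), fill = "shift in EBRs") +
    theme_bw()
}
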