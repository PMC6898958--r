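# End-to-end driver: simulate an ancestor and derived lineages, build
# anchors for every ordered genome pair, chain HSBs, detect and merge EBRs
# per genome, and test EBR features — one deterministic run from a single
# config and seed.

#' Default pipeline configuration
#'
#' All parameters default to the package's documented choices; unknown keys
#' in a user config are rejected. Every value is echoed into the run
#' report.
#'
#' @return Nested list of parameter blocks.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    simulate = list(
      n_chromosomes = 6, length_mean = 6e6, length_cv = 0.2,
      gene_rate = 12, gc_target = 0.42,
      repeat_mix = c("LINE-L1" = 0.15, "SINE" = 0.08, "LTR-ERV1" = 0.04),
      with_sequence = TRUE,
      lineages = list(
        list(id = "g1", n_events = 6,
             rates = c(fission = 3, inversion = 2, translocation = 1,
                       fusion = 0)),
        list(id = "g2", n_events = 10,
             rates = c(fission = 5, inversion = 2, translocation = 1,
                       fusion = 0)),
        list(id = "g3", n_events = 3,
             rates = c(fission = 2, inversion = 1, translocation = 0,
                       fusion = 0)))),
    anchors = list(dropout = 0, jitter_sd = 0, micro_inversion_rate = 0),
    chain = list(max_gap = 2e6, min_anchors = 3, min_span = 5e5,
                 micro_tolerance = 2e5),
    ebr = list(fission_only = FALSE),
    features = list(window = 1e5, n_perm = 200),
    output_dir = NULL,
    log_level = "info")
}

.validate_config <- function(config, template = default_config(),
                             path = "config") {
  unknown <- setdiff(names(config), names(template))
  if (length(unknown)) {
    abort(sprintf("unknown %s key(s): %s", path,
                  paste(unknown, collapse = ", ")))
  }
  for (nm in names(config)) {
    if (is.list(template[[nm]]) && !is.null(names(template[[nm]])) &&
        is.list(config[[nm]]) && nm != "lineages") {
      .validate_config(config[[nm]], template[[nm]],
                       paste(path, nm, sep = "$"))
    }
  }
  invisible(config)
}

#' Read a pipeline config from YAML
#'
#' @param path YAML file; keys override [default_config()].
#' @return Full config list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  .validate_config(user)
  .merge_config(user)
}

# modifyList merges list elements recursively, which would splice user
# lineages into the default three; lineages are replaced wholesale instead
.merge_config <- function(config) {
  merged <- utils::modifyList(default_config(), config)
  if (!is.null(config$simulate$lineages)) {
    merged$simulate$lineages <- config$simulate$lineages
  }
  merged
}

# anchors between two derived genomes, joined through shared ancestor genes
.cross_anchors <- function(sim_a, sim_b, dropout = 0, jitter_sd = 0,
                           micro_inversion_rate = 0) {
  oa <- sim_a$truth$ortholog_map
  ob <- sim_b$truth$ortholog_map
  pairs <- inner_join(
    oa |> select(gene = "gene_a", chrom_a = "chrom_b", start_a = "start_b",
                 end_a = "end_b", strand_a = "strand_b"),
    ob |> select(gene = "gene_a", chrom_b = "chrom_b", start_b = "start_b",
                 end_b = "end_b", strand_b = "strand_b"),
    by = "gene") |>
    mutate(gene_a = .data$gene, gene_b = .data$gene) |>
    select(-"gene")
  emit_anchors(pairs, dropout = dropout, jitter_sd = jitter_sd,
               micro_inversion_rate = micro_inversion_rate,
               karyotype_a = sim_a$derived$karyotype,
               karyotype_b = sim_b$derived$karyotype)
}

#' Run the full simulate-to-enrichment pipeline
#'
#' Simulates one ancestor and several derived lineages, builds anchors for
#' every ordered pair of derived genomes (each genome serving as the EBR
#' target against every other), chains HSBs, detects EBRs, merges the EBR
#' sets per genome, and tests EBR genomic features. Deterministic given
#' config + seed. When `output_dir` is set, stage outputs are written as
#' TSV and reused on rerun if the config (hash) is unchanged.
#'
#' @param config Config list (see [default_config()]).
#' @return A `breakscape_run` object: config echo plus per-stage results.
#' @export
run_pipeline <- function(config = default_config()) {
  .validate_config(config)
  config <- .merge_config(config)
  cfg_hash <- rlang::hash(config)
  out_dir <- config$output_dir
  cache_file <- NULL
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "cache"), recursive = TRUE,
               showWarnings = FALSE)
    cache_file <- file.path(out_dir, "cache", paste0("run_", cfg_hash, ".rds"))
    if (file.exists(cache_file)) {
      inform("reusing cached run for unchanged config")
      return(readRDS(cache_file))
    }
  }
  set.seed(config$seed)
  sc <- config$simulate

  anc <- simulate_ancestor(
    n_chromosomes = sc$n_chromosomes, length_mean = sc$length_mean,
    length_cv = sc$length_cv, gene_rate = sc$gene_rate,
    repeat_mix = sc$repeat_mix, gc_target = sc$gc_target,
    with_sequence = sc$with_sequence,
    seed = (config$seed * 13L) %% .Machine$integer.max)

  sims <- purrr::imap(sc$lineages, function(lin, k) {
    apply_rearrangements(anc, n_events = lin$n_events,
                         rates = unlist(lin$rates),
                         derived_id = lin$id,
                         seed = (config$seed * 101L + k) %% 2147483647L)
  })
  names(sims) <- purrr::map_chr(sc$lineages, "id")
  ids <- names(sims)

  comparisons <- list()
  for (ti in ids) {
    for (oi in setdiff(ids, ti)) {
      label <- paste0(ti, "_vs_", oi)
      anchors <- .cross_anchors(sims[[ti]], sims[[oi]],
                                dropout = config$anchors$dropout,
                                jitter_sd = config$anchors$jitter_sd,
                                micro_inversion_rate =
                                  config$anchors$micro_inversion_rate)
      hsbs <- chain_anchors(anchors,
                            max_gap = config$chain$max_gap,
                            min_anchors = config$chain$min_anchors,
                            min_span = config$chain$min_span,
                            micro_tolerance = config$chain$micro_tolerance)
      ebrs <- detect_ebrs(hsbs, target = "a",
                          fission_only = config$ebr$fission_only,
                          genome_id = ti, comparison = label)
      comparisons[[label]] <- list(
        label = label, target = ti, other = oi,
        n_anchors = nrow(anchors), hsbs = hsbs, ebrs = ebrs,
        hsb_summary = hsb_table(hsbs, sims[[ti]]$derived$karyotype,
                                sims[[oi]]$derived$karyotype),
        fission_events = count_fission_events(hsbs, "a"))
    }
  }

  merged <- purrr::map(ids, function(ti) {
    sets <- purrr::keep(comparisons, ~.x$target == ti)
    m <- sets[[1]]$ebrs
    overlaps <- 0L
    for (k in seq_along(sets)[-1]) {
      res <- merge_ebr_sets(m, sets[[k]]$ebrs)
      m <- res$ebrs
      overlaps <- overlaps + res$overlap_pair_count
    }
    list(genome = ti, ebrs = m, overlap_pair_count = overlaps,
         summary = ebr_summary(m))
  })
  names(merged) <- ids

  feature_tests <- purrr::map(ids, function(ti) {
    sim <- sims[[ti]]
    ebrs <- merged[[ti]]$ebrs
    if (!nrow(ebrs)) return(NULL)
    list(
      stats = compare_ebr_features(sim$derived, ebrs,
                                   window = config$features$window,
                                   per_chromosome = FALSE),
      repeats = repeat_family_enrichment(
        sim$derived$features, ebrs, sim$derived$karyotype,
        n_perm = config$features$n_perm),
      genes_in_ebrs = genes_in_regions(sim$derived$features, ebrs))
  })
  names(feature_tests) <- ids

  report <- structure(list(
    version = as.character(packageVersion("breakscape")),
    config = config, config_hash = cfg_hash,
    genomes = ids,
    n_comparisons = length(comparisons),
    comparisons = comparisons,
    merged_ebrs = merged,
    feature_tests = feature_tests), class = "breakscape_run")

  if (!is.null(out_dir)) {
    hdr <- sprintf("breakscape %s config=%s", report$version, cfg_hash)
    for (cmp in comparisons) {
      write_result_tsv(cmp$hsbs,
                       file.path(out_dir, paste0("hsbs_", cmp$label, ".tsv")),
                       comment = hdr)
      write_result_tsv(cmp$ebrs,
                       file.path(out_dir, paste0("ebrs_", cmp$label, ".tsv")),
                       comment = hdr)
    }
    for (m in merged) {
      write_result_tsv(m$ebrs,
                       file.path(out_dir,
                                 paste0("ebrs_union_", m$genome, ".tsv")),
                       comment = hdr)
    }
    jsonlite::write_json(glance(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    saveRDS(report, cache_file)
  }
  report
}

#' @export
print.breakscape_run <- function(x, ...) {
  cat(sprintf("<breakscape_run> v%s  config %s\n", x$version, x$config_hash))
  cat(sprintf("  genomes: %s; %d pairwise comparisons\n",
              paste(x$genomes, collapse = ", "), x$n_comparisons))
  for (cmp in x$comparisons) {
    cat(sprintf("  %-12s anchors %4d  HSBs %3d  EBRs %3d  fissions %d\n",
                cmp$label, cmp$n_anchors, nrow(cmp$hsbs), nrow(cmp$ebrs),
                cmp$fission_events))
  }
  for (m in x$merged_ebrs) {
    cat(sprintf("  union %-6s EBRs %3d (mean %.1f kb)\n", m$genome,
                m$summary$stats$n, m$summary$stats$mean_length / 1e3))
  }
  invisible(x)
}
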