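# Genomic features of regions and enrichment testing: GC content, gene
# density and repeat coverage in fixed windows, Mann-Whitney comparison of
# EBR windows against all windows of the chromosome/genome, repeat-family
# fold enrichment with a permutation null, and hypergeometric gene-set
# overrepresentation with Benjamini-Hochberg correction.

#' GC fraction of sequences or regions
#'
#' Computes (G+C)/(A+C+G+T); `N` bases are excluded from the denominator.
#' A region consisting entirely of `N` yields `NA` with a warning.
#'
#' @param seqs A [karyotype()] with sequences, a `DNAStringSet`, or a
#'   character vector of sequences.
#' @param regions Optional tibble `chrom`, `start`, `end` (0-based
#'   half-open); when `NULL`, one value per sequence is returned.
#' @return Numeric vector of GC fractions (per region or per sequence).
#' @export
gc_content <- function(seqs, regions = NULL) {
  if (inherits(seqs, "karyotype")) {
    if (is.null(seqs$seqs)) abort("karyotype carries no sequences")
    seqs <- seqs$seqs
  }
  if (!methods::is(seqs, "DNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(toupper(seqs))
  }
  gc_one <- function(s) {
    f <- Biostrings::letterFrequency(s, c("G", "C", "A", "T"))
    denom <- sum(f)
    if (denom == 0) NA_real_ else sum(f[c("G", "C")]) / denom
  }
  if (is.null(regions)) {
    out <- purrr::map_dbl(seq_along(seqs), function(i) gc_one(seqs[[i]]))
    if (anyNA(out)) warn("all-N sequence: GC undefined (NA)")
    return(out)
  }
  .check_cols(regions, c("chrom", "start", "end"), "`regions`")
  lens <- Biostrings::width(seqs)[match(regions$chrom, names(seqs))]
  if (anyNA(lens) || any(regions$start < 0) || any(regions$end > lens)) {
    abort("region outside sequence bounds")
  }
  out <- purrr::pmap_dbl(regions[c("chrom", "start", "end")],
                         function(chrom, start, end) {
    gc_one(Biostrings::subseq(seqs[[chrom]], start + 1, end))
  })
  if (anyNA(out)) warn("all-N region: GC undefined (NA)")
  out
}

#' Feature density or coverage per region
#'
#' Count mode counts features whose midpoint falls in the region and
#' reports counts per Mb; coverage mode reports the fraction of region
#' bases covered by (clipped) feature intervals.
#'
#' @param track Feature-track tibble.
#' @param regions Tibble `chrom`, `start`, `end`.
#' @param mode `"count_per_mb"` or `"coverage_fraction"`.
#' @param category,family Optional filters on the track.
#' @return Numeric vector, one value per region.
#' @export
region_density <- function(track, regions,
                           mode = c("count_per_mb", "coverage_fraction"),
                           category = NULL, family = NULL) {
  mode <- match.arg(mode)
  .check_cols(regions, c("chrom", "start", "end"), "`regions`")
  if (any(regions$end <= regions$start)) abort("zero-length region")
  if (!is.null(category)) track <- filter(track, .data$category == !!category)
  if (!is.null(family)) track <- filter(track, .data$family == !!family)
  vapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    f <- track |> filter(.data$chrom == r$chrom)
    if (mode == "count_per_mb") {
      mid <- (f$start + f$end) / 2
      sum(mid >= r$start & mid < r$end) / ((r$end - r$start) / 1e6)
    } else {
      if (!nrow(f)) return(0)
      # union coverage: overlapping features never count twice
      cov <- IRanges::intersect(IRanges::reduce(.ir(f$start, f$end)),
                                .ir(r$start, r$end))
      sum(IRanges::width(cov)) / (r$end - r$start)
    }
  }, numeric(1))
}

#' Mann-Whitney U test
#'
#' U counts pairs with `x > y` plus half the ties. The exact method
#' enumerates the permutation null (tie-free samples with
#' `n1 * n2 <= 10000`; falls back to the normal approximation otherwise);
#' the normal method uses the tie-corrected variance with continuity
#' correction.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (`x` relative
#'   to `y`).
#' @param method `"auto"` (exact when permitted), `"exact"` or `"normal"`.
#' @return One-row tibble: `statistic` (U), `z`, `p_value`, `method`,
#'   `alternative`, `n1`, `n2`, `direction` (`"higher"`, `"lower"` or
#'   `"none"`, the sign of the mean-rank shift of `x`).
#' @export
mann_whitney_u <- function(x, y,
                           alternative = c("two.sided", "less", "greater"),
                           method = c("auto", "exact", "normal")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) abort("both samples must be non-empty")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- switch(method,
    exact = TRUE, normal = FALSE,
    auto = !has_ties && n1 * n2 <= 10000)
  if (use_exact && (has_ties || n1 * n2 > 10000)) {
    warn("exact method unavailable (ties or too large); using normal")
    use_exact <- FALSE
  }
  mu <- n1 * n2 / 2
  if (use_exact) {
    p <- switch(alternative,
      two.sided = min(1, 2 * min(pwilcox(u, n1, n2),
                                 pwilcox(u - 1, n1, n2, lower.tail = FALSE))),
      greater = pwilcox(u - 1, n1, n2, lower.tail = FALSE),
      less = pwilcox(u, n1, n2))
    z <- NA_real_
    used <- "exact"
  } else {
    nt <- table(c(x, y))
    N <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(nt^3 - nt) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1; z <- 0
    } else {
      cc <- switch(alternative,
        two.sided = sign(u - mu) * 0.5, greater = 0.5, less = -0.5)
      z <- (u - mu - cc) / sqrt(sigma2)
      p <- switch(alternative,
        two.sided = 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)),
        greater = pnorm(z, lower.tail = FALSE),
        less = pnorm(z))
      p <- min(1, p)
    }
    used <- "normal"
  }
  tibble(statistic = u, z = if (used == "normal") z else NA_real_,
         p_value = p, method = used, alternative = alternative,
         n1 = n1, n2 = n2,
         direction = if (u > mu) "higher" else if (u < mu) "lower" else "none")
}

#' Tile a karyotype into fixed windows and measure features
#'
#' @param genome A `sim_genome` list (`karyotype` + `features`) or a
#'   [karyotype()]; sequences, when present, supply per-window GC.
#' @param features Feature track (taken from `genome` when omitted).
#' @param window Window size in bases.
#' @return Tibble: `chrom`, `start`, `end`, `gene_density`, `repeat_cov`,
#'   `gc` (NA without sequences).
#' @export
window_features <- function(genome, features = NULL, window = 1e5) {
  kar <- if (inherits(genome, "karyotype")) genome else genome$karyotype
  features <- features %||% genome$features
  .assert_scalar_num(window, "window", min = 1e3)
  wins <- purrr::map2(kar$chromosomes$chrom, kar$chromosomes$length,
                      function(cn, L) {
    s <- seq(0, L - 1, by = window)
    tibble(chrom = cn, start = s, end = pmin(s + window, L))
  }) |> list_rbind()
  wins$gene_density <- region_density(features, wins, "count_per_mb",
                                      category = "gene")
  wins$repeat_cov <- region_density(features, wins, "coverage_fraction",
                                    category = "repeat")
  wins$gc <- if (is.null(kar$seqs)) NA_real_ else gc_content(kar$seqs, wins)
  wins
}

#' Compare genomic features in EBRs against the whole genome
#'
#' Tiles each chromosome into fixed windows, measures gene density, GC and
#' repeat coverage per window, and runs a Mann-Whitney test of the windows
#' overlapping any EBR (`x`) against all windows (`y`) — per chromosome and
#' pooled genome-wide.
#'
#' @inheritParams window_features
#' @param ebrs EBR tibble on the same genome.
#' @param window Window size in bases (>= 1 kb; default 100 kb).
#' @param per_chromosome Also emit per-chromosome tests.
#' @param method Mann-Whitney p-value route (see
#'   [mann_whitney_u()]); `"auto"` uses the exact null when permitted.
#' @param baseline `"all"` compares EBR windows against all windows of the
#'   chromosome/genome (the literal "versus the whole chromosome" reading;
#'   slightly conservative because the EBR windows are part of the
#'   baseline); `"complement"` compares against the non-EBR windows only
#'   (disjoint samples, exactly calibrated type-I error).
#' @param windows Optional precomputed [window_features()] table (saves
#'   recomputation across repeated calls with different EBR sets).
#' @return Tibble of class `ebr_feature_stats`: `scope`, `feature`,
#'   `n_ebr_windows`, `n_windows`, `statistic`, `p_value`, `direction`.
#' @export
compare_ebr_features <- function(genome, ebrs, features = NULL,
                                 window = 1e5, per_chromosome = TRUE,
                                 baseline = c("all", "complement"),
                                 method = c("auto", "exact", "normal"),
                                 windows = NULL) {
  baseline <- match.arg(baseline)
  method <- match.arg(method)
  wins <- windows %||% window_features(genome, features, window)
  in_ebr <- rep(FALSE, nrow(wins))
  for (cn in unique(ebrs$chrom)) {
    e <- ebrs |> filter(.data$chrom == cn)
    sel <- wins$chrom == cn
    hit <- IRanges::overlapsAny(.ir(wins$start[sel], wins$end[sel]),
                                .ir(e$start, e$end))
    in_ebr[sel][hit] <- TRUE
  }
  if (!any(in_ebr)) {
    warn("no windows overlap any EBR; returning NA results")
  }
  feats <- c(gene_density = "gene_density", gc = "gc",
             repeat_cov = "repeat_cov")
  feats <- feats[!vapply(feats, function(f) all(is.na(wins[[f]])), logical(1))]
  run <- function(scope, sel_x, sel_y) {
    purrr::map(names(feats), function(f) {
      xv <- wins[[f]][sel_x]; yv <- wins[[f]][sel_y]
      if (!length(xv) || !length(yv)) {
        return(tibble(scope = scope, feature = f, n_ebr_windows = length(xv),
                      n_windows = length(yv), statistic = NA_real_,
                      p_value = NA_real_, direction = NA_character_))
      }
      mw <- mann_whitney_u(xv, yv, method = method)
      tibble(scope = scope, feature = f, n_ebr_windows = length(xv),
             n_windows = length(yv), statistic = mw$statistic,
             p_value = mw$p_value, direction = mw$direction)
    }) |> list_rbind()
  }
  base_sel <- if (baseline == "all") rep(TRUE, nrow(wins)) else !in_ebr
  out <- run("genome", in_ebr, base_sel)
  if (per_chromosome) {
    per <- purrr::map(unique(wins$chrom), function(cn) {
      sel <- wins$chrom == cn
      if (!any(in_ebr & sel)) return(NULL)
      run(cn, in_ebr & sel, sel & base_sel)
    }) |> discard(is.null) |> list_rbind()
    out <- bind_rows(out, per)
  }
  structure(out, class = c("ebr_feature_stats", class(tibble())))
}

#' Repeat-family enrichment in EBRs
#'
#' Fold change of each repeat family's coverage fraction in EBR bases over
#' its genome-wide coverage fraction, with a permutation p-value from
#' random placements of a length-matched region set on the same karyotype.
#'
#' @param track Feature track with family-labelled repeat records.
#' @param ebrs EBR tibble.
#' @param kar The [karyotype()] the regions live on.
#' @param n_perm Number of random placements (>= 1 recommended 1000).
#' @param seed Optional integer seed.
#' @return Tibble ranked by fold: `family`, `ebr_fraction`,
#'   `genome_fraction`, `fold`, `p_value`.
#' @export
repeat_family_enrichment <- function(track, ebrs, kar, n_perm = 1000,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  reps <- track |> filter(.data$category == "repeat")
  if (!nrow(reps)) abort("track contains no repeat records")
  fams <- unique(reps$family)
  total_len <- sum(kar$chromosomes$length)
  genome_frac <- vapply(fams, function(f) {
    sum((reps$end - reps$start)[reps$family == f]) / total_len
  }, numeric(1))

  # per-family, per-chromosome reduced repeat ranges, computed once
  fam_ir <- lapply(fams, function(f) {
    r <- reps |> filter(.data$family == f)
    lapply(split(r, r$chrom), function(rr) IRanges::reduce(.ir(rr$start,
                                                               rr$end)))
  })
  names(fam_ir) <- fams
  frac_in <- function(regions) {
    span <- sum(regions$end - regions$start)
    by_chr <- split(regions, regions$chrom)
    reg_ir <- lapply(by_chr, function(qq) IRanges::reduce(.ir(qq$start,
                                                              qq$end)))
    vapply(fams, function(f) {
      tot <- 0
      for (cn in names(reg_ir)) {
        rr <- fam_ir[[f]][[cn]]
        if (is.null(rr)) next
        tot <- tot + sum(IRanges::width(IRanges::intersect(rr, reg_ir[[cn]])))
      }
      tot / span
    }, numeric(1))
  }

  obs <- frac_in(ebrs)
  lens <- ebrs$end - ebrs$start
  chrom_w <- kar$chromosomes$length
  exceed <- rep(0, length(fams))
  for (p in seq_len(n_perm)) {
    cn <- sample(kar$chromosomes$chrom, length(lens), replace = TRUE,
                 prob = chrom_w)
    maxs <- .chrom_length(kar, cn) - lens
    keep <- maxs >= 0
    s <- floor(runif(sum(keep), 0, maxs[keep] + 1))
    rnd <- tibble(chrom = cn[keep], start = s, end = s + lens[keep])
    exceed <- exceed + (frac_in(rnd) >= obs)
  }
  tibble(family = fams, ebr_fraction = unname(obs),
         genome_fraction = unname(genome_frac),
         fold = unname(ifelse(genome_frac > 0, obs / genome_frac, NA_real_)),
         p_value = unname((1 + exceed) / (1 + n_perm))) |>
    arrange(dplyr::desc(.data$fold))
}

#' Hypergeometric gene-set overrepresentation
#'
#' Upper-tail hypergeometric p per term with Benjamini-Hochberg adjustment
#' across the tested terms. Terms are intersected with the universe; the
#' query must be a subset of the universe.
#'
#' @param query_genes Character vector of query gene ids.
#' @param annotation Named list of term -> gene-id vectors (or a tibble with
#'   columns `term` and `gene`).
#' @param universe Character vector: the background gene universe.
#' @return Tibble: `term`, `term_size`, `overlap`, `p_value`, `q_value`,
#'   ordered by p.
#' @export
geneset_overrepresentation <- function(query_genes, annotation, universe) {
  universe <- unique(universe)
  if (!length(universe)) abort("`universe` is empty")
  query_genes <- unique(query_genes)
  outside <- setdiff(query_genes, universe)
  if (length(outside)) {
    abort(sprintf("%d query gene(s) not in the universe (e.g. %s)",
                  length(outside), outside[1]))
  }
  if (is.data.frame(annotation)) {
    .check_cols(annotation, c("term", "gene"), "`annotation`")
    annotation <- split(annotation$gene, annotation$term)
  }
  n_u <- length(universe)
  n_q <- length(query_genes)
  out <- purrr::imap(annotation, function(genes, term) {
    gs <- intersect(unique(genes), universe)
    k <- length(intersect(gs, query_genes))
    p <- phyper(k - 1, length(gs), n_u - length(gs), n_q, lower.tail = FALSE)
    tibble(term = term, term_size = length(gs), overlap = k, p_value = p)
  }) |> list_rbind()
  out |>
    mutate(q_value = p.adjust(.data$p_value, method = "BH")) |>
    arrange(.data$p_value)
}

#' Genes overlapping a region set
#'
#' Genes whose interval overlaps any region by at least one base,
#' deduplicated, in deterministic (chromosome, start) order.
#'
#' @param track Feature track (gene records are used).
#' @param regions Tibble `chrom`, `start`, `end`.
#' @return Character vector of gene names.
#' @export
genes_in_regions <- function(track, regions) {
  genes <- track |> filter(.data$category == "gene")
  if (!nrow(genes) || !nrow(regions)) return(character(0))
  hit <- rep(FALSE, nrow(genes))
  for (cn in unique(regions$chrom)) {
    sel <- genes$chrom == cn
    if (!any(sel)) next
    r <- regions |> filter(.data$chrom == cn)
    hit[sel] <- IRanges::overlapsAny(.ir(genes$start[sel], genes$end[sel]),
                                     .ir(r$start, r$end))
  }
  g <- genes[hit, ] |> arrange(.data$chrom, .data$start)
  unique(g$name)
}
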