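# Karyotype rearrangement simulator.
#
# The simulator produces an "ancestral" multi-chromosome genome with gene and
# repeat tracks, applies fission / fusion / inversion / translocation events
# with exact ground-truth breakpoint recording, and emits ortholog anchors
# with configurable dropout, positional jitter and micro-inversions. It is
# the recovery oracle for the synteny / breakpoint modules: every analysis
# claim the package makes is testable against the planted truth.

.default_family_len <- c("LINE-L1" = 3000, "SINE" = 300, "LTR-ERV1" = 1500)

.family_mean_len <- function(family) {
  len <- .default_family_len[family]
  ifelse(is.na(len), 1000, len)
}

# fixed-composition motif: exactly round(width * gc) G/C letters, shuffled
.repeat_motif <- function(gc, width = 61L) {
  n_gc <- round(width * gc)
  letters <- c(sample(c("G", "C"), n_gc, replace = TRUE),
               sample(c("A", "T"), width - n_gc, replace = TRUE))
  paste(sample(letters), collapse = "")
}

.random_seq <- function(len, gc) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# place non-overlapping random intervals on [0, L). The interval COUNT is
# Poisson (mean = target_bases / mean interval length), not filled to an
# exact coverage target: a fixed per-chromosome coverage sum would induce
# negative correlation between windows and bias window-based null tests.
.place_intervals <- function(chrom_len, target_bases, len_fun,
                             occupied = NULL, max_rounds = 60L) {
  kept <- if (is.null(occupied)) IRanges::IRanges() else occupied
  mean_len <- max(1, mean(len_fun(200L)))
  n_target <- rpois(1, target_bases / mean_len)
  out_start <- numeric(0)
  out_end <- numeric(0)
  for (round in seq_len(max_rounds)) {
    need <- n_target - length(out_start)
    if (need <= 0) break
    lens <- len_fun(max(8L, ceiling(need * 1.3)))
    lens <- pmin(pmax(lens, 30), chrom_len)
    starts <- floor(runif(length(lens), 0, chrom_len - lens))
    cand <- .ir(starts, starts + lens)
    cand <- cand[!IRanges::overlapsAny(cand, kept)]
    # also drop candidates overlapping each other (keep first of each clash)
    if (length(cand) > 1) {
      self_hit <- IRanges::findOverlaps(cand, drop.self = TRUE,
                                        drop.redundant = TRUE)
      drop <- unique(S4Vectors::subjectHits(self_hit))
      if (length(drop)) cand <- cand[-drop]
    }
    if (!length(cand)) next
    if (length(cand) > need) cand <- cand[seq_len(need)]
    kept <- c(kept, cand)
    out_start <- c(out_start, IRanges::start(cand) - 1)
    out_end <- c(out_end, IRanges::end(cand))
  }
  tibble(start = out_start, end = out_end) |> arrange(.data$start)
}

#' Simulate an ancestral genome with gene and repeat tracks
#'
#' Generates a multi-chromosome karyotype with i.i.d. nucleotide sequences at
#' a target GC fraction, repeat intervals overwritten with family-specific
#' repetitive text, and non-overlapping gene models. Repeat text is generated
#' at a (configurably) elevated GC, with the background composition adjusted
#' so that the genome-wide GC still hits `gc_target`.
#'
#' @param n_chromosomes Number of chromosomes (>= 1).
#' @param length_mean,length_cv Mean and coefficient of variation of
#'   chromosome lengths in bases (gamma model; `length_cv = 0` gives equal
#'   lengths).
#' @param gene_rate Genes per Mb.
#' @param gene_length Two-element range of gene lengths in bases.
#' @param gene_placement `"poisson"` (random starts) or `"regular"` (evenly
#'   spaced genes at `1e6 / gene_rate` bases apart — convenient when a fixed
#'   anchor spacing is wanted).
#' @param repeat_mix Named numeric vector mapping repeat family to target
#'   genome coverage fraction; fractions must sum to < 1.
#' @param gc_target Genome-wide GC fraction in (0, 1).
#' @param repeat_gc_shift GC elevation of repeat text over `gc_target`.
#' @param with_sequence Generate nucleotide sequences (set `FALSE` for large
#'   coordinate-only simulations).
#' @param seed Optional integer seed; identical seed gives identical output.
#'
#' @return A list of class `sim_genome` with elements `karyotype`
#'   ([karyotype()]), `features` (feature-track tibble) and `params`.
#' @export
simulate_ancestor <- function(n_chromosomes = 10, length_mean = 10e6,
                              length_cv = 0.2, gene_rate = 10,
                              gene_length = c(2e3, 2e4),
                              gene_placement = c("poisson", "regular"),
                              repeat_mix = c("LINE-L1" = 0.15, "SINE" = 0.08,
                                             "LTR-ERV1" = 0.04),
                              gc_target = 0.42, repeat_gc_shift = 0.12,
                              with_sequence = TRUE, seed = NULL) {
  gene_placement <- match.arg(gene_placement)
  if (!is_scalar_integerish(n_chromosomes) || n_chromosomes < 1) {
    abort("`n_chromosomes` must be a positive integer")
  }
  .assert_scalar_num(gene_rate, "gene_rate", min = 0)
  .assert_scalar_num(gc_target, "gc_target", min = 1e-6, max = 1 - 1e-6)
  if (length(repeat_mix)) {
    if (is.null(names(repeat_mix)) || any(!nzchar(names(repeat_mix)))) {
      abort("`repeat_mix` must be a named vector of family fractions")
    }
    if (any(repeat_mix < 0) || sum(repeat_mix) >= 1) {
      abort("repeat fractions must be >= 0 and sum to < 1")
    }
  }
  if (!is.null(seed)) set.seed(seed)

  lens <- if (length_cv <= 0) rep(length_mean, n_chromosomes) else {
    shape <- 1 / length_cv^2
    round(rgamma(n_chromosomes, shape = shape, scale = length_mean / shape))
  }
  lens <- pmax(lens, 2e5)
  chroms <- tibble(chrom = sprintf("chr%d", seq_len(n_chromosomes)),
                   length = as.numeric(lens))

  rep_gc <- min(max(gc_target + repeat_gc_shift, 0.02), 0.98)
  motifs <- setNames(
    lapply(names(repeat_mix), function(f) .repeat_motif(rep_gc)),
    names(repeat_mix))

  gene_id <- 0L
  track <- purrr::map2(chroms$chrom, chroms$length, function(cn, L) {
    # genes
    if (gene_placement == "regular" && gene_rate > 0) {
      spacing <- 1e6 / gene_rate
      glen <- round(mean(gene_length))
      starts <- seq(spacing / 2, L - glen - 1, by = spacing)
      genes <- tibble(start = floor(starts), end = floor(starts) + glen)
    } else {
      n_g <- rpois(1, gene_rate * L / 1e6)
      if (n_g > 0) {
        glen <- round(runif(n_g, gene_length[1], gene_length[2]))
        gs <- sort(floor(runif(n_g, 0, L - max(glen))))
        genes <- tibble(start = gs, end = gs + glen)
        # drop overlapping successors so genes never overlap genes
        keep <- rep(TRUE, n_g)
        open_end <- -1
        for (i in seq_len(n_g)) {
          if (genes$start[i] < open_end) keep[i] <- FALSE
          else open_end <- genes$end[i]
        }
        genes <- genes[keep, ]
      } else genes <- tibble(start = numeric(0), end = numeric(0))
    }
    if (nrow(genes)) {
      ids <- sprintf("g%05d", gene_id + seq_len(nrow(genes)))
      gene_id <<- gene_id + nrow(genes)
      genes <- genes |>
        mutate(chrom = cn, name = ids, category = "gene",
               family = NA_character_,
               strand = sample(c("+", "-"), n(), replace = TRUE))
    } else genes <- .empty_track()

    # repeats: non-overlapping within the repeat category, across families
    occupied <- IRanges::IRanges()
    reps <- purrr::imap(repeat_mix, function(frac, fam) {
      mlen <- .family_mean_len(fam)
      placed <- .place_intervals(
        L, target_bases = frac * L,
        len_fun = function(n) round(rgamma(n, shape = 9, scale = mlen / 9)),
        occupied = occupied)
      occupied <<- c(occupied, .ir(placed$start, placed$end))
      placed |> mutate(chrom = cn, category = "repeat", family = fam,
                       strand = "+")
    }) |> list_rbind()
    if (nrow(reps)) {
      reps <- reps |> mutate(name = sprintf("%s_%s_%d", cn, .data$family,
                                            row_number()))
    } else reps <- .empty_track()
    bind_rows(genes, reps)
  }) |> list_rbind() |>
    select("chrom", "start", "end", "name", "category", "family", "strand") |>
    arrange(match(.data$chrom, chroms$chrom), .data$start)

  seqs <- NULL
  if (with_sequence) {
    rep_total <- sum(repeat_mix)
    bg_gc <- if (rep_total > 0) {
      min(max((gc_target - rep_total * rep_gc) / (1 - rep_total), 0.01), 0.99)
    } else gc_target
    motif_chars <- lapply(motifs, function(m) strsplit(m, "")[[1]])
    seqs <- Biostrings::DNAStringSet(setNames(
      purrr::map2_chr(chroms$chrom, chroms$length, function(cn, L) {
        v <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                    prob = c((1 - bg_gc) / 2, bg_gc / 2, bg_gc / 2,
                             (1 - bg_gc) / 2))
        reps <- track |> filter(.data$chrom == cn, .data$category == "repeat")
        for (i in seq_len(nrow(reps))) {
          w <- reps$end[i] - reps$start[i]
          v[(reps$start[i] + 1):reps$end[i]] <-
            rep_len(motif_chars[[reps$family[i]]], w)
        }
        paste(v, collapse = "")
      }), chroms$chrom))
  }

  structure(
    list(karyotype = karyotype("anc", chroms, seqs),
         features = track,
         params = list(gene_rate = gene_rate, repeat_mix = repeat_mix,
                       gc_target = gc_target, repeat_gc = rep_gc,
                       motifs = motifs, gene_length = gene_length)),
    class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("<sim_genome> %s: %d chromosomes, %d genes, %d repeats\n",
              x$karyotype$genome_id, nrow(x$karyotype$chromosomes),
              sum(x$features$category == "gene"),
              sum(x$features$category == "repeat")))
  invisible(x)
}

## ---- segment machinery -----------------------------------------------------
## a derived chromosome is an ordered tibble of ancestor segments
## (chrom_anc, start, end, strand); derived coordinates are implicit in the
## running order. Ancestor coordinates never change, so ground-truth
## breakpoints are recorded in the ancestor frame once and stay valid.

.seg_new <- function(chrom, len) {
  tibble(chrom_anc = chrom, start = 0, end = len, strand = "+")
}

.seg_len <- function(segs) sum(segs$end - segs$start)

# split a segment tibble at derived position `pos` (0 < pos < L)
.seg_cut <- function(segs, pos) {
  w <- segs$end - segs$start
  off <- cumsum(c(0, w))[seq_len(nrow(segs))]
  i <- findInterval(pos - 1e-9, off)  # segment containing base pos-1
  d <- pos - off[i]                   # internal offset, 0 < d <= w[i]
  left <- segs[seq_len(i - 1), , drop = FALSE]
  right <- segs[-seq_len(i), , drop = FALSE]
  seg <- segs[i, , drop = FALSE]
  if (d < w[i]) {
    if (seg$strand == "+") {
      l <- seg |> mutate(end = .data$start + d)
      r <- seg |> mutate(start = .data$start + d)
    } else {
      l <- seg |> mutate(start = .data$end - d)
      r <- seg |> mutate(end = .data$end - d)
    }
    list(left = bind_rows(left, l), right = bind_rows(r, right))
  } else {
    list(left = bind_rows(left, seg), right = right)
  }
}

# ancestor-frame location of the boundary before derived base `pos`
.seg_anc_boundary <- function(segs, pos) {
  w <- segs$end - segs$start
  off <- cumsum(c(0, w))[seq_len(nrow(segs))]
  i <- findInterval(pos - 1e-9, off)
  d <- pos - off[i]
  seg <- segs[i, ]
  anc <- if (seg$strand == "+") seg$start + d else seg$end - d
  list(chrom = seg$chrom_anc, pos = anc)
}

.seg_invert <- function(segs) {
  segs[rev(seq_len(nrow(segs))), ] |>
    mutate(strand = if_else(.data$strand == "+", "-", "+"))
}

# map ancestor-frame features onto one derived chromosome; genes that would
# be clipped by a segment boundary are dropped (only possible when
# gene-disrupting breakpoints were allowed)
.seg_map_features <- function(segs, track) {
  if (!nrow(track)) return(.empty_track())
  w <- segs$end - segs$start
  off <- cumsum(c(0, w))[seq_len(nrow(segs))]
  pieces <- purrr::map(seq_len(nrow(segs)), function(i) {
    seg <- segs[i, ]
    f <- track |> filter(.data$chrom == seg$chrom_anc,
                         .data$end > seg$start, .data$start < seg$end)
    if (!nrow(f)) return(NULL)
    cs <- pmax(f$start, seg$start)
    ce <- pmin(f$end, seg$end)
    clipped <- cs > f$start | ce < f$end
    keep <- !(clipped & f$category == "gene")
    f <- f[keep, ]; cs <- cs[keep]; ce <- ce[keep]
    if (!nrow(f)) return(NULL)
    if (seg$strand == "+") {
      ds <- off[i] + (cs - seg$start)
      de <- off[i] + (ce - seg$start)
      str <- f$strand
    } else {
      ds <- off[i] + (seg$end - ce)
      de <- off[i] + (seg$end - cs)
      str <- if_else(f$strand == "+", "-", "+")
    }
    f |> mutate(start = ds, end = de, strand = str)
  })
  out <- list_rbind(discard(pieces, is.null))
  if (is.null(out) || !nrow(out)) return(.empty_track())
  arrange(out, .data$start)
}

# derived-frame sequence of one chromosome from the ancestor sequences
.seg_sequence <- function(segs, seqs) {
  pieces <- purrr::map(seq_len(nrow(segs)), function(i) {
    seg <- segs[i, ]
    piece <- Biostrings::subseq(seqs[[seg$chrom_anc]],
                                start = seg$start + 1, end = seg$end)
    if (seg$strand == "-") piece <- Biostrings::reverseComplement(piece)
    piece
  })
  do.call(Biostrings::xscat, pieces)
}

# sample a cut position on one derived chromosome: uniform over positions
# strictly inside the chromosome, excluding gene interiors when
# `avoid_genes`, with positions inside repeat intervals upweighted by `bias`
.sample_cut <- function(segs, track, avoid_genes, bias) {
  L <- .seg_len(segs)
  if (L < 2) abort("chromosome too short for a breakpoint")
  feats <- .seg_map_features(segs, track)
  allowed <- IRanges::IRanges(1, L - 1)
  if (avoid_genes) {
    g <- feats |> filter(.data$category == "gene", .data$end - .data$start > 1)
    if (nrow(g)) {
      allowed <- IRanges::setdiff(allowed,
                                  IRanges::IRanges(g$start + 1, g$end - 1))
    }
  }
  if (!length(allowed)) abort("no breakpoint position available outside genes")
  r <- feats |> filter(.data$category == "repeat", .data$end - .data$start > 1)
  rep_part <- if (nrow(r) && bias != 1) {
    IRanges::intersect(allowed, IRanges::IRanges(r$start + 1, r$end - 1))
  } else IRanges::IRanges()
  plain <- IRanges::setdiff(allowed, rep_part)
  parts <- c(plain, rep_part)
  wts <- c(IRanges::width(plain), IRanges::width(rep_part) * bias)
  k <- sample.int(length(parts), 1, prob = wts)
  IRanges::start(parts)[k] + sample.int(IRanges::width(parts)[k], 1) - 1L
}

## ---- rearrangement application --------------------------------------------

#' Apply chromosome rearrangements with ground-truth recording
#'
#' Applies an explicit plan (or randomly sampled events) of fissions,
#' fusions, inversions and translocations to an ancestral genome. Total
#' genome length is conserved exactly; genes survive intact with updated
#' coordinates and strand (unless `avoid_genes = FALSE`); every cut site is
#' recorded as a 2-bp ground-truth breakpoint interval in the ancestor
#' coordinate frame — the frame in which evolutionary breakpoint regions are
#' detected when the derived genome is aligned back.
#'
#' @param ancestor A `sim_genome` from [simulate_ancestor()], or a list with
#'   elements `karyotype` and `features`.
#' @param plan Explicit event list: each element a list with `kind`
#'   (`"fission"`, `"fusion"`, `"inversion"`, `"translocation"`) and, per
#'   kind, `chrom`/`pos` (fission), `chroms` (fusion), `chrom`/`start`/`end`
#'   (inversion), `chroms`/`pos` (translocation, two cut positions).
#'   Positions are derived-frame at the moment the event is applied.
#' @param n_events,rates When `plan` is `NULL`, the number of random events
#'   and per-kind sampling weights.
#' @param breakpoint_bias Multiplier on the sampling weight of candidate cut
#'   positions inside repeat intervals (1 = uniform).
#' @param avoid_genes Keep breakpoints outside gene bodies (default `TRUE`).
#' @param flank_enrichment Optional named list/vector of density factors used
#'   to plant extra features around breakpoints, e.g.
#'   `list(gene = 2, "LINE-L1" = 3)`: feature density in breakpoint flanks is
#'   raised to factor times the genome-wide density. The enriched ancestor is
#'   returned alongside the derived genome.
#' @param flank_width Half-width in bases of the enrichment flank windows.
#' @param derived_id Genome id of the derived karyotype.
#' @param seed Optional integer seed.
#'
#' @return A list of class `rearrangement_sim`: `ancestor` and `derived`
#'   (each `karyotype` + `features`), and `truth` with `events`,
#'   `breakpoints` (ancestor-frame 2-bp intervals) and `ortholog_map`.
#' @export
apply_rearrangements <- function(ancestor, plan = NULL, n_events = NULL,
                                 rates = c(fission = 1, fusion = 0,
                                           inversion = 0, translocation = 0),
                                 breakpoint_bias = 1, avoid_genes = TRUE,
                                 flank_enrichment = NULL, flank_width = 1e5,
                                 derived_id = NULL, seed = NULL) {
  kar <- ancestor$karyotype
  track <- ancestor$features
  if (is.null(kar) || is.null(track)) {
    abort("`ancestor` must have `karyotype` and `features` elements")
  }
  .assert_scalar_num(breakpoint_bias, "breakpoint_bias", min = 0)
  if (!is.null(seed)) set.seed(seed)
  derived_id <- derived_id %||% paste0(kar$genome_id, "_der")

  chrs <- setNames(
    purrr::map2(kar$chromosomes$chrom, kar$chromosomes$length, .seg_new),
    kar$chromosomes$chrom)

  if (is.null(plan)) {
    if (is.null(n_events)) abort("give either `plan` or `n_events`")
    if (any(rates < 0) || sum(rates) <= 0) abort("invalid `rates`")
    plan <- replicate(n_events,
                      list(kind = sample(names(rates), 1, prob = rates)),
                      simplify = FALSE)
  }

  events <- list()
  bps <- list()
  ev_id <- 0L

  record_bp <- function(segs, pos, kind, event_id) {
    b <- .seg_anc_boundary(segs, pos)
    L <- .chrom_length(kar, b$chrom)
    bps[[length(bps) + 1]] <<- tibble(
      event_id = event_id, kind = kind, chrom = b$chrom,
      start = max(0, b$pos - 1), end = min(L, b$pos + 1))
  }

  for (ev in plan) {
    ev_id <- ev_id + 1L
    kind <- ev$kind %||% abort("each plan event needs a `kind`")
    if (kind == "fusion" && is.null(ev$chroms) && length(chrs) < 2) {
      kind <- "fission"  # randomly drawn fusion with one chromosome left
    }
    if (kind == "fission") {
      cn <- ev$chrom %||% {
        w <- purrr::map_dbl(chrs, .seg_len)
        sample(names(chrs), 1, prob = w)
      }
      if (!cn %in% names(chrs)) abort(sprintf("unknown chromosome '%s'", cn))
      segs <- chrs[[cn]]
      L <- .seg_len(segs)
      pos <- ev$pos %||% .sample_cut(segs, track, avoid_genes, breakpoint_bias)
      if (pos <= 0 || pos >= L) abort("fission breakpoint outside chromosome")
      if (avoid_genes) .check_cut_outside_genes(segs, track, pos)
      record_bp(segs, pos, "fission", ev_id)
      halves <- .seg_cut(segs, pos)
      prods <- paste0(cn, c(".1", ".2"))
      chrs[[cn]] <- NULL
      chrs[[prods[1]]] <- halves$left
      chrs[[prods[2]]] <- halves$right
      events[[ev_id]] <- tibble(event_id = ev_id, kind = kind,
                                generation = ev_id, chrom = cn, pos = pos,
                                chrom2 = NA_character_, pos2 = NA_real_,
                                products = paste(prods, collapse = ","))
    } else if (kind == "fusion") {
      cns <- ev$chroms %||% sample(names(chrs), 2)
      if (length(cns) != 2 || !all(cns %in% names(chrs)) || cns[1] == cns[2]) {
        abort("fusion needs two distinct existing chromosomes")
      }
      prod <- paste0(cns[1], "+", cns[2])
      merged <- bind_rows(chrs[[cns[1]]], chrs[[cns[2]]])
      chrs[[cns[1]]] <- NULL
      chrs[[cns[2]]] <- NULL
      chrs[[prod]] <- merged
      events[[ev_id]] <- tibble(event_id = ev_id, kind = kind,
                                generation = ev_id, chrom = cns[1],
                                pos = NA_real_, chrom2 = cns[2],
                                pos2 = NA_real_, products = prod)
    } else if (kind == "inversion") {
      cn <- ev$chrom %||% {
        w <- purrr::map_dbl(chrs, .seg_len)
        sample(names(chrs), 1, prob = w)
      }
      segs <- chrs[[cn]]
      L <- .seg_len(segs)
      if (is.null(ev$start)) {
        p <- sort(c(.sample_cut(segs, track, avoid_genes, breakpoint_bias),
                    .sample_cut(segs, track, avoid_genes, breakpoint_bias)))
        while (p[1] == p[2]) {
          p[2] <- .sample_cut(segs, track, avoid_genes, breakpoint_bias)
          p <- sort(p)
        }
      } else p <- c(ev$start, ev$end)
      if (p[1] <= 0 || p[2] >= L || p[1] >= p[2]) {
        abort("inversion breakpoints outside chromosome or inverted")
      }
      if (avoid_genes) {
        .check_cut_outside_genes(segs, track, p[1])
        .check_cut_outside_genes(segs, track, p[2])
      }
      record_bp(segs, p[1], "inversion", ev_id)
      record_bp(segs, p[2], "inversion", ev_id)
      a <- .seg_cut(segs, p[1])
      b <- .seg_cut(a$right, p[2] - p[1])
      chrs[[cn]] <- bind_rows(a$left, .seg_invert(b$left), b$right)
      events[[ev_id]] <- tibble(event_id = ev_id, kind = kind,
                                generation = ev_id, chrom = cn, pos = p[1],
                                chrom2 = cn, pos2 = p[2], products = cn)
    } else if (kind == "translocation") {
      cns <- ev$chroms %||% sample(names(chrs), 2)
      if (length(cns) != 2 || !all(cns %in% names(chrs)) || cns[1] == cns[2]) {
        abort("translocation needs two distinct existing chromosomes")
      }
      p <- ev$pos %||% c(
        .sample_cut(chrs[[cns[1]]], track, avoid_genes, breakpoint_bias),
        .sample_cut(chrs[[cns[2]]], track, avoid_genes, breakpoint_bias))
      L1 <- .seg_len(chrs[[cns[1]]]); L2 <- .seg_len(chrs[[cns[2]]])
      if (p[1] <= 0 || p[1] >= L1 || p[2] <= 0 || p[2] >= L2) {
        abort("translocation breakpoint outside chromosome")
      }
      if (avoid_genes) {
        .check_cut_outside_genes(chrs[[cns[1]]], track, p[1])
        .check_cut_outside_genes(chrs[[cns[2]]], track, p[2])
      }
      record_bp(chrs[[cns[1]]], p[1], "translocation", ev_id)
      record_bp(chrs[[cns[2]]], p[2], "translocation", ev_id)
      c1 <- .seg_cut(chrs[[cns[1]]], p[1])
      c2 <- .seg_cut(chrs[[cns[2]]], p[2])
      prods <- paste0(cns, "t")
      chrs[[cns[1]]] <- NULL
      chrs[[cns[2]]] <- NULL
      chrs[[prods[1]]] <- bind_rows(c1$left, c2$right)
      chrs[[prods[2]]] <- bind_rows(c2$left, c1$right)
      events[[ev_id]] <- tibble(event_id = ev_id, kind = kind,
                                generation = ev_id, chrom = cns[1],
                                pos = p[1], chrom2 = cns[2], pos2 = p[2],
                                products = paste(prods, collapse = ","))
    } else {
      abort(sprintf("unknown event kind '%s'", kind))
    }
  }

  events <- if (length(events)) list_rbind(events) else
    tibble(event_id = integer(), kind = character(), generation = integer(),
           chrom = character(), pos = numeric(), chrom2 = character(),
           pos2 = numeric(), products = character())
  bps <- if (length(bps)) {
    list_rbind(bps) |> mutate(bp_id = sprintf("bp%03d", row_number())) |>
      select("bp_id", "event_id", "kind", "chrom", "start", "end")
  } else {
    tibble(bp_id = character(), event_id = integer(), kind = character(),
           chrom = character(), start = numeric(), end = numeric())
  }

  # plant elevated feature density in ancestor-frame breakpoint flanks
  anc_kar <- kar
  if (!is.null(flank_enrichment) && nrow(bps)) {
    enriched <- .enrich_flanks(kar, track, bps, flank_enrichment, flank_width,
                               motifs = ancestor$params$motifs,
                               rep_gc = ancestor$params$repeat_gc %||% 0.5)
    anc_kar <- enriched$karyotype
    track <- enriched$features
  }

  # materialize derived genome
  d_chroms <- tibble(chrom = names(chrs),
                     length = purrr::map_dbl(chrs, .seg_len))
  d_track <- purrr::imap(chrs, function(segs, cn) {
    .seg_map_features(segs, track) |> mutate(chrom = cn)
  }) |> list_rbind()
  d_seqs <- NULL
  if (!is.null(anc_kar$seqs)) {
    d_seqs <- Biostrings::DNAStringSet(
      purrr::map(chrs, .seg_sequence, seqs = anc_kar$seqs))
    names(d_seqs) <- names(chrs)
  }
  d_kar <- karyotype(derived_id, d_chroms, d_seqs)

  anc_genes <- track |> filter(.data$category == "gene")
  der_genes <- d_track |> filter(.data$category == "gene")
  ortho <- inner_join(
    anc_genes |> select(gene_a = "name", chrom_a = "chrom",
                        start_a = "start", end_a = "end", strand_a = "strand"),
    der_genes |> select(gene_b = "name", chrom_b = "chrom",
                        start_b = "start", end_b = "end", strand_b = "strand"),
    by = c(gene_a = "gene_b"), keep = TRUE) |>
    select("gene_a", "gene_b", "chrom_a", "start_a", "end_a", "strand_a",
           "chrom_b", "start_b", "end_b", "strand_b")

  structure(
    list(ancestor = list(karyotype = anc_kar, features = track),
         derived = list(karyotype = d_kar, features = d_track),
         truth = list(events = events, breakpoints = bps,
                      ortholog_map = ortho)),
    class = "rearrangement_sim")
}

#' @export
print.rearrangement_sim <- function(x, ...) {
  cat(sprintf(
    "<rearrangement_sim> %s -> %s: %d event(s), %d truth breakpoint(s), %d ortholog pair(s)\n",
    x$ancestor$karyotype$genome_id, x$derived$karyotype$genome_id,
    nrow(x$truth$events), nrow(x$truth$breakpoints),
    nrow(x$truth$ortholog_map)))
  invisible(x)
}

.check_cut_outside_genes <- function(segs, track, pos) {
  feats <- .seg_map_features(segs, track)
  g <- feats |> filter(.data$category == "gene",
                       .data$start < pos, pos < .data$end)
  if (nrow(g)) {
    abort(sprintf("breakpoint at %d falls inside gene body '%s'",
                  as.integer(pos), g$name[1]))
  }
  invisible(TRUE)
}

# add genes / family repeats around ancestor-frame breakpoints so that the
# local density reaches factor x genome-wide density; repeat additions
# overwrite the ancestor sequence with the family motif
.enrich_flanks <- function(kar, track, bps, factors, flank_width,
                           motifs = NULL, rep_gc = 0.5) {
  factors <- unlist(factors)
  total_len <- sum(kar$chromosomes$length)
  seqs <- if (is.null(kar$seqs)) NULL else as.list(kar$seqs)
  new_feats <- list()
  gene_ct <- 0L

  windows <- bps |>
    mutate(mid = (.data$start + .data$end) / 2) |>
    mutate(ws = pmax(0, .data$mid - flank_width),
           we = pmin(.chrom_length(kar, .data$chrom), .data$mid + flank_width))

  for (i in seq_len(nrow(windows))) {
    wchrom <- windows$chrom[i]; ws <- windows$ws[i]; we <- windows$we[i]
    wlen <- we - ws
    # hard exclusions: every breakpoint 2bp interval on this chromosome
    excl <- bps |> filter(.data$chrom == wchrom)
    excl_ir <- .ir(excl$start, excl$end)
    local <- track |> filter(.data$chrom == wchrom)
    for (nm in names(factors)) {
      f <- factors[[nm]]
      if (f <= 1) next
      if (nm == "gene") {
        dens <- sum(track$category == "gene") / total_len
        have <- local |> filter(.data$category == "gene",
                                (.data$start + .data$end) / 2 >= ws,
                                (.data$start + .data$end) / 2 < we) |> nrow()
        n_add <- max(0, round(f * dens * wlen - have))
        if (n_add == 0) next
        glen <- round(median(track$end[track$category == "gene"] -
                               track$start[track$category == "gene"]) %||% 5e3)
        occ <- local |> filter(.data$category == "gene")
        occupied <- c(.ir(occ$start, occ$end), excl_ir)
        placed <- .place_intervals(wlen, n_add * glen,
                                   len_fun = function(n) rep(glen, n),
                                   occupied = IRanges::shift(occupied, -ws))
        if (!nrow(placed)) next
        placed <- placed |> mutate(start = .data$start + ws,
                                   end = .data$end + ws) |>
          filter(.data$end <= we)
        if (!nrow(placed)) next
        add <- placed |> mutate(
          chrom = wchrom,
          name = sprintf("ge%05d", gene_ct + row_number()),
          category = "gene", family = NA_character_,
          strand = sample(c("+", "-"), n(), replace = TRUE))
        gene_ct <- gene_ct + nrow(add)
        new_feats[[length(new_feats) + 1]] <- add
        local <- bind_rows(local, add)
      } else {
        fam_bases <- sum((track$end - track$start)[
          track$category == "repeat" & track$family == nm])
        gfrac <- fam_bases / total_len
        have <- local |> filter(.data$category == "repeat",
                                .data$family == nm,
                                .data$end > ws, .data$start < we)
        have_bases <- sum(pmin(have$end, we) - pmax(have$start, ws))
        need <- max(0, f * gfrac * wlen - have_bases)
        if (need <= 0) next
        occ <- local |> filter(.data$category == "repeat")
        occupied <- c(.ir(occ$start, occ$end), excl_ir)
        mlen <- .family_mean_len(nm)
        placed <- .place_intervals(
          wlen, need,
          len_fun = function(n) round(rgamma(n, shape = 9, scale = mlen / 9)),
          occupied = IRanges::shift(occupied, -ws))
        if (!nrow(placed)) next
        placed <- placed |> mutate(start = .data$start + ws,
                                   end = .data$end + ws) |>
          filter(.data$end <= we)
        if (!nrow(placed)) next
        add <- placed |> mutate(
          chrom = wchrom,
          name = sprintf("%s_%s_e%d_%d", wchrom, nm, i, row_number()),
          category = "repeat", family = nm, strand = "+")
        new_feats[[length(new_feats) + 1]] <- add
      }
    }
  }

  added <- list_rbind(new_feats)
  track2 <- bind_rows(track, added) |> arrange(.data$chrom, .data$start)
  # overwrite ancestor sequence under newly planted repeats, one pass per
  # chromosome (char-vector edit: substr<- on long strings copies them)
  if (!is.null(seqs) && !is.null(added) && nrow(added)) {
    new_reps <- added |> filter(.data$category == "repeat")
    for (cn in unique(new_reps$chrom)) {
      v <- strsplit(as.character(seqs[[cn]]), "")[[1]]
      rr <- new_reps |> filter(.data$chrom == cn)
      for (j in seq_len(nrow(rr))) {
        motif <- motifs[[rr$family[j]]] %||% .repeat_motif(rep_gc)
        w <- rr$end[j] - rr$start[j]
        v[(rr$start[j] + 1):rr$end[j]] <- rep_len(strsplit(motif, "")[[1]], w)
      }
      seqs[[cn]] <- paste(v, collapse = "")
    }
  }
  kar2 <- karyotype(kar$genome_id, kar$chromosomes,
                    if (is.null(seqs)) NULL else
                      Biostrings::DNAStringSet(unlist(lapply(seqs, as.character))))
  list(karyotype = kar2, features = track2)
}

## ---- anchors from truth ----------------------------------------------------

#' Emit ortholog anchors with dropout, jitter and micro-inversions
#'
#' Converts an ortholog gene map (e.g. from a [apply_rearrangements()] truth
#' set) into an anchor table, optionally dropping pairs at random, jittering
#' interval coordinates, and flipping the orientation of a fraction of
#' anchors to emulate micro-inversions.
#'
#' @param ortholog_map Tibble with columns `gene_a`, `gene_b`, `chrom_a`,
#'   `start_a`, `end_a`, `strand_a`, `chrom_b`, `start_b`, `end_b`,
#'   `strand_b`.
#' @param dropout Fraction of pairs removed at random, in `[0, 1)`.
#' @param jitter_sd Gaussian SD in bases applied to interval endpoints;
#'   jittered intervals never leave the chromosome when karyotypes are given.
#' @param micro_inversion_rate Fraction of anchors whose orientation is
#'   flipped (coordinates untouched).
#' @param karyotype_a,karyotype_b Karyotypes used to clamp jittered
#'   coordinates (required when `jitter_sd > 0`).
#' @param seed Optional integer seed.
#'
#' @return An anchor tibble: `anchor_id`, `chrom_a`, `start_a`, `end_a`,
#'   `chrom_b`, `start_b`, `end_b`, `orientation`, `weight`, `source`.
#' @export
emit_anchors <- function(ortholog_map, dropout = 0, jitter_sd = 0,
                         micro_inversion_rate = 0, karyotype_a = NULL,
                         karyotype_b = NULL, seed = NULL) {
  if (is.null(ortholog_map) || !nrow(ortholog_map)) {
    abort("`ortholog_map` is empty")
  }
  .assert_scalar_num(dropout, "dropout", min = 0, max = 1 - 1e-9)
  .assert_scalar_num(jitter_sd, "jitter_sd", min = 0)
  .assert_scalar_num(micro_inversion_rate, "micro_inversion_rate", 0, 1)
  if (jitter_sd > 0 && (is.null(karyotype_a) || is.null(karyotype_b))) {
    abort("karyotypes are required to clamp jittered coordinates")
  }
  if (!is.null(seed)) set.seed(seed)

  keep <- runif(nrow(ortholog_map)) >= dropout
  a <- ortholog_map[keep, , drop = FALSE]
  if (!nrow(a)) abort("all ortholog pairs dropped; lower `dropout`")

  jit <- function(start, end, len) {
    s <- start + round(rnorm(length(start), 0, jitter_sd))
    e <- end + round(rnorm(length(end), 0, jitter_sd))
    lo <- pmin(s, e); hi <- pmax(s, e)
    lo <- pmax(0, pmin(lo, len - 1))
    hi <- pmax(lo + 1, pmin(hi, len))
    list(start = lo, end = hi)
  }
  if (jitter_sd > 0) {
    la <- .chrom_length(karyotype_a, a$chrom_a)
    lb <- .chrom_length(karyotype_b, a$chrom_b)
    ja <- jit(a$start_a, a$end_a, la)
    jb <- jit(a$start_b, a$end_b, lb)
    a$start_a <- ja$start; a$end_a <- ja$end
    a$start_b <- jb$start; a$end_b <- jb$end
  }
  ori <- if_else(a$strand_a == a$strand_b, "+", "-")
  if (micro_inversion_rate > 0) {
    flip <- runif(nrow(a)) < micro_inversion_rate
    ori[flip] <- if_else(ori[flip] == "+", "-", "+")
  }
  tibble(anchor_id = sprintf("a%06d", seq_len(nrow(a))),
         chrom_a = a$chrom_a, start_a = a$start_a, end_a = a$end_a,
         chrom_b = a$chrom_b, start_b = a$start_b, end_b = a$end_b,
         orientation = ori,
         weight = pmin(a$end_a - a$start_a, a$end_b - a$start_b),
         source = "ortholog")
}

## ---- scaffolding simulation helpers ---------------------------------------

#' Shred a karyotype into scaffolds with known layout
#'
#' Cuts each chromosome into consecutive scaffolds, optionally flipping some
#' to the minus strand, and returns the scaffold-level karyotype together
#' with the true layout — the oracle for the scaffold assignment and
#' ordering functions.
#'
#' @param kar A [karyotype()] (sequences optional).
#' @param pieces_per_chrom Mean number of scaffolds per chromosome (>= 1).
#' @param flip_fraction Fraction of scaffolds emitted reverse-complemented.
#' @param min_piece Minimum scaffold length in bases (cut positions are
#'   drawn on a `min_piece` grid).
#' @param seed Optional integer seed.
#' @return List with `karyotype` (scaffolds, shuffled order) and `truth`
#'   tibble (`scaffold`, `chrom`, `start`, `end`, `rank`, `orientation`).
#' @export
shred_karyotype <- function(kar, pieces_per_chrom = 10, flip_fraction = 0.3,
                            min_piece = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  truth <- purrr::map2(kar$chromosomes$chrom, kar$chromosomes$length,
                       function(cn, L) {
    k <- max(1, rpois(1, pieces_per_chrom))
    cand <- if (min_piece > 1) {
      seq(min_piece, L - min_piece, by = min_piece)
    } else seq_len(L - 1)
    cuts <- sort(sample(cand, min(k - 1, length(cand))))
    bounds <- c(0, cuts, L)
    tibble(chrom = cn, start = bounds[-length(bounds)], end = bounds[-1],
           rank = seq_len(length(bounds) - 1))
  }) |> list_rbind() |>
    mutate(scaffold = sprintf("sc%04d", row_number()),
           orientation = if_else(runif(n()) < flip_fraction, "-", "+"))
  seqs <- NULL
  if (!is.null(kar$seqs)) {
    seqs <- Biostrings::DNAStringSet(purrr::pmap(
      list(truth$chrom, truth$start, truth$end, truth$orientation),
      function(cn, s, e, o) {
        piece <- Biostrings::subseq(kar$seqs[[cn]], s + 1, e)
        if (o == "-") piece <- Biostrings::reverseComplement(piece)
        piece
      }))
    names(seqs) <- truth$scaffold
  }
  ord <- sample(nrow(truth))
  sc_chroms <- tibble(chrom = truth$scaffold,
                      length = truth$end - truth$start)[ord, ]
  list(karyotype = karyotype(paste0(kar$genome_id, "_scaf"), sc_chroms,
                             if (is.null(seqs)) NULL else seqs[ord]),
       truth = truth)
}

#' Simulate a flow-sorted chromosome coverage matrix
#'
#' Builds a scaffold-by-library mean-depth matrix as produced by mapping
#' reads from flow-sorted chromosome libraries onto scaffolds: depth is high
#' in the library of the scaffold's own chromosome and near background
#' elsewhere. Libraries can be merged to emulate chromosomes that could not
#' be resolved during sorting.
#'
#' @param shred_truth Truth tibble from [shred_karyotype()].
#' @param merged_libraries Optional list of character vectors; chromosomes in
#'   one vector share a single (mixed) library named by joining their names
#'   with `"+"`.
#' @param depth_range Range of per-library on-target depths (the study's
#'   libraries varied several-fold, so columns are not comparable raw).
#' @param background_depth Mean off-target depth.
#' @param seed Optional integer seed.
#' @return A tibble: `scaffold` column plus one numeric column per library.
#' @export
simulate_coverage_matrix <- function(shred_truth, merged_libraries = NULL,
                                     depth_range = c(60, 260),
                                     background_depth = 1.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chroms <- unique(shred_truth$chrom)
  lib_of <- setNames(chroms, chroms)
  if (!is.null(merged_libraries)) {
    for (grp in merged_libraries) {
      lib_of[grp] <- paste(grp, collapse = "+")
    }
  }
  libs <- unique(unname(lib_of))
  lib_depth <- setNames(runif(length(libs), depth_range[1], depth_range[2]),
                        libs)
  m <- matrix(rgamma(nrow(shred_truth) * length(libs), shape = 4,
                     scale = background_depth / 4),
              nrow = nrow(shred_truth), ncol = length(libs),
              dimnames = list(shred_truth$scaffold, libs))
  for (i in seq_len(nrow(shred_truth))) {
    lib <- lib_of[[shred_truth$chrom[i]]]
    m[i, lib] <- rgamma(1, shape = 100, scale = lib_depth[lib] / 100)
  }
  bind_cols(tibble(scaffold = shred_truth$scaffold), as_tibble(m))
}
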