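# Format I/O. Internal coordinates are 0-based half-open everywhere; BED
# stays 0-based half-open on disk, GFF3 is converted to/from its 1-based
# closed convention at this boundary.

#' Read / write FASTA as a karyotype
#'
#' Sequences are uppercased on read; duplicate headers are rejected.
#'
#' @param path FASTA file path.
#' @param genome_id Genome label (defaults to the file stem).
#' @return [karyotype()] with sequences.
#' @export
read_fasta <- function(path, genome_id = NULL) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  s <- Biostrings::readDNAStringSet(path)
  if (!length(s)) abort("empty FASTA file")
  nm <- sub("\\s.*$", "", names(s))
  dup <- nm[duplicated(nm)]
  if (length(dup)) {
    abort(sprintf("duplicate FASTA header '%s'", dup[1]))
  }
  s <- Biostrings::DNAStringSet(toupper(as.character(s)))
  names(s) <- nm
  genome_id <- genome_id %||% sub("\\.(fa|fasta|fna)(\\.gz)?$", "",
                                  basename(path))
  karyotype(genome_id,
            tibble(chrom = nm, length = Biostrings::width(s)), s)
}

#' @rdname read_fasta
#' @param kar A [karyotype()] with sequences.
#' @export
write_fasta <- function(kar, path) {
  if (is.null(kar$seqs)) abort("karyotype carries no sequences")
  Biostrings::writeXStringSet(kar$seqs, path)
  invisible(path)
}

#' Read / write feature intervals (BED or GFF3)
#'
#' BED repeat records carry the family in the name column as
#' `"family:LINE-L1"`; gene records carry the gene id. GFF3 uses the type
#' column for the category and `Name`/`family` attributes.
#'
#' @param path File path.
#' @param dialect `"bed"` or `"gff3"`.
#' @return A feature-track tibble (0-based half-open).
#' @export
read_intervals <- function(path, dialect = c("bed", "gff3")) {
  dialect <- match.arg(dialect)
  gr <- rtracklayer::import(path, format = if (dialect == "bed") "BED"
                            else "GFF3")
  start0 <- GenomicRanges::start(gr) - 1
  end0 <- GenomicRanges::end(gr)
  if (any(end0 <= start0)) {
    abort(sprintf("invalid interval at record %d", which(end0 <= start0)[1]))
  }
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "+"
  if (dialect == "bed") {
    nm <- gr$name %||% sprintf("feat%d", seq_along(gr))
    is_rep <- startsWith(nm, "family:")
    tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
           start = start0, end = end0,
           name = if_else(is_rep, sprintf("rep%05d", seq_along(nm)), nm),
           category = if_else(is_rep, "repeat", "gene"),
           family = if_else(is_rep, sub("^family:", "", nm), NA_character_),
           strand = strand)
  } else {
    md <- S4Vectors::mcols(gr)
    type <- as.character(md$type %||% rep("gene", length(gr)))
    fam <- as.character(md$family %||% rep(NA_character_, length(gr)))
    nm <- as.character(md$Name %||% md$ID %||%
                         sprintf("feat%d", seq_along(gr)))
    tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
           start = start0, end = end0, name = nm,
           category = if_else(type == "repeat", "repeat", "gene"),
           family = fam, strand = strand)
  }
}

#' @rdname read_intervals
#' @param track Feature-track tibble.
#' @export
write_intervals <- function(track, path, dialect = c("bed", "gff3")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed") {
    lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                     track$chrom, as.integer(track$start),
                     as.integer(track$end),
                     if_else(track$category == "repeat",
                             paste0("family:", track$family), track$name),
                     0L, track$strand %||% "+")
    writeLines(lines, path)
  } else {
    attrs <- sprintf("ID=%s;Name=%s%s", track$name, track$name,
                     if_else(track$category == "repeat" & !is.na(track$family),
                             paste0(";family=", track$family), ""))
    lines <- c("##gff-version 3",
               sprintf("%s\tbreakscape\t%s\t%d\t%d\t.\t%s\t.\t%s",
                       track$chrom, track$category,
                       as.integer(track$start) + 1L, as.integer(track$end),
                       track$strand %||% "+", attrs))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read / write an ortholog pair map as TSV
#'
#' Columns: `gene_a`, `gene_b`, `chrom_a`, `start_a`, `end_a`, `strand_a`,
#' `chrom_b`, `start_b`, `end_b`, `strand_b` (0-based half-open).
#'
#' @param path TSV file path.
#' @return Ortholog map tibble.
#' @export
read_orthologs <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  .check_cols(x, c("gene_a", "gene_b", "chrom_a", "start_a", "end_a",
                   "strand_a", "chrom_b", "start_b", "end_b", "strand_b"),
              "ortholog TSV")
  x
}

#' @rdname read_orthologs
#' @param pairs Ortholog map tibble.
#' @export
write_orthologs <- function(pairs, path) {
  readr::write_tsv(pairs, path)
  invisible(path)
}

#' Write a tabular result (anchors, HSBs, EBRs) as TSV
#'
#' List columns (`anchor_ids`, `sources`) are flattened to comma-separated
#' strings.
#'
#' @param x Tibble to write.
#' @param path File path.
#' @param comment Optional header comment lines (prefixed with `#`).
#' @export
write_result_tsv <- function(x, path, comment = NULL) {
  x <- mutate(x, across(dplyr::where(is.list),
                        ~purrr::map_chr(.x, paste, collapse = ",")))
  if (!is.null(comment)) {
    writeLines(paste0("# ", comment), path)
    readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(x, path)
  }
  invisible(path)
}

#' @rdname write_result_tsv
#' @export
read_result_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}
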