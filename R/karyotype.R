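#' Karyotype: a set of named chromosomes with lengths and optional sequences
#'
#' The karyotype is the coordinate frame for every downstream operation.
#' Coordinates are 0-based and half-open throughout the package; converters
#' to the 1-based conventions of GFF3 and AGP live at the I/O boundary.
#'
#' @param genome_id Short label for the genome (e.g. `"anc"`, `"pandaLike"`).
#' @param chromosomes A data frame with columns `chrom` (unique names) and
#'   `length` (bases, >= 1).
#' @param seqs Optional [Biostrings::DNAStringSet] named by chromosome whose
#'   widths equal the declared lengths.
#'
#' @return An object of class `karyotype`: a list with elements `genome_id`,
#'   `chromosomes` (tibble) and `seqs` (`DNAStringSet` or `NULL`).
#' @export
karyotype <- function(genome_id, chromosomes, seqs = NULL) {
  if (!is_scalar_character(genome_id)) abort("`genome_id` must be a string")
  chromosomes <- as_tibble(chromosomes)
  .check_cols(chromosomes, c("chrom", "length"), "`chromosomes`")
  chromosomes$chrom <- as.character(chromosomes$chrom)
  chromosomes$length <- as.numeric(unname(chromosomes$length))
  if (anyDuplicated(chromosomes$chrom)) {
    abort("chromosome names must be unique within a genome")
  }
  if (any(chromosomes$length < 1)) abort("chromosome lengths must be >= 1")
  if (!is.null(seqs)) {
    if (!methods::is(seqs, "DNAStringSet")) {
      seqs <- Biostrings::DNAStringSet(seqs)
    }
    if (!setequal(names(seqs), chromosomes$chrom)) {
      abort("`seqs` names must match chromosome names")
    }
    seqs <- seqs[chromosomes$chrom]
    if (!all(Biostrings::width(seqs) == chromosomes$length)) {
      abort("sequence widths must equal declared chromosome lengths")
    }
  }
  structure(
    list(genome_id = genome_id,
         chromosomes = chromosomes[, c("chrom", "length")],
         seqs = seqs),
    class = "karyotype"
  )
}

#' @export
print.karyotype <- function(x, ...) {
  cat(sprintf("<karyotype> %s: %d chromosome(s), %.2f Mb total%s\n",
              x$genome_id, nrow(x$chromosomes),
              sum(x$chromosomes$length) / 1e6,
              if (is.null(x$seqs)) " (no sequences)" else ""))
  print(x$chromosomes, n = 5)
  invisible(x)
}

.chrom_length <- function(kar, chrom) {
  len <- kar$chromosomes$length[match(chrom, kar$chromosomes$chrom)]
  if (anyNA(len)) {
    abort(sprintf("unknown chromosome(s): %s",
                  paste(unique(chrom[is.na(len)]), collapse = ", ")))
  }
  len
}

#' Validate a feature track against a karyotype
#'
#' A feature track is a tibble of gene and repeat annotations with columns
#' `chrom`, `start`, `end` (0-based half-open), `name`, `category`
#' (`"gene"` or `"repeat"`), `family` (repeat family, `NA` for genes) and
#' `strand`.
#'
#' @param track A feature-track tibble.
#' @param kar A [karyotype()] the coordinates must fit in.
#' @return The track, invisibly, after validation.
#' @export
validate_track <- function(track, kar) {
  .check_cols(track, c("chrom", "start", "end", "name", "category"), "track")
  if (any(track$start < 0) || any(track$start >= track$end)) {
    abort("track intervals must satisfy 0 <= start < end")
  }
  len <- .chrom_length(kar, track$chrom)
  if (any(track$end > len)) abort("track interval exceeds chromosome length")
  if (!all(track$category %in% c("gene", "repeat"))) {
    abort("track `category` must be 'gene' or 'repeat'")
  }
  invisible(track)
}

.empty_track <- function() {
  tibble(chrom = character(), start = numeric(), end = numeric(),
         name = character(), category = character(), family = character(),
         strand = character())
}
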