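#' Read a multi-record FASTA file
#'
#' Parses FASTA via Biostrings, then normalises: record names are stripped at
#' the first whitespace, sequences upper-cased and `U` converted to `T`.
#' Duplicate record names (after stripping) are an error, as is an empty file
#' or a file whose first non-blank line is not a `>` header.
#'
#' @param path path to a FASTA file.
#' @return a named character vector mapping record name to sequence.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1 human", "acgu"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    abort(paste0("FASTA format error in ", path, ": file is empty"))
  }
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    abort(sprintf("FASTA format error in %s at line %d: expected '>' header",
                  path, nonblank[1]))
  }
  bad <- nonblank[!startsWith(trimws(lines[nonblank]), ">") &
                    grepl("[^ACGTUNacgtun]", trimws(lines[nonblank]))]
  if (length(bad)) {
    abort(sprintf("FASTA format error in %s at line %d: non-nucleotide characters",
                  path, bad[1]))
  }
  ss <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) {
    abort(sprintf("duplicate FASTA record name: %s", nm[duplicated(nm)][1]))
  }
  out <- norm_seq(as.character(ss), what = "FASTA sequence")
  names(out) <- nm
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file path.
#' @param width line-wrap width in nucleotides.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read introns from a BED6 file and attach sense-strand sequences
#'
#' Coordinates are BED-style 0-based half-open on disk. The returned
#' sequence is the intron on the sense strand of transcription: for
#' minus-strand records the genomic slice is reverse-complemented, so the
#' last two characters of `seq` are the 3' splice site AG whenever the
#' annotation is correct.
#'
#' @param path path to a BED6 file (chrom, start, end, name, score, strand).
#' @param fasta named character vector from [read_fasta()].
#' @return a tibble with one row per intron: `name`, `chrom`, `start`,
#'   `end`, `strand`, `seq`, `len`, plus placeholder metadata columns
#'   `gene_id`, `upstream_exon_len`, `downstream_exon_len`,
#'   `transcript_len` (NA unless supplied elsewhere).
#' @export
read_bed_introns <- function(path, fasta) {
  if (!file.exists(path)) abort(paste0("BED file not found: ", path))
  bed <- readr::read_tsv(path,
    col_names = c("chrom", "start", "end", "name", "score", "strand"),
    col_types = "ciicdc", comment = "#", progress = FALSE)
  if (nrow(bed) == 0L) abort(paste0("BED file has no records: ", path))
  bad <- which(!(bed$strand %in% c("+", "-")))
  if (length(bad)) {
    abort(sprintf("BED record '%s': strand must be + or -", bed$name[bad[1]]))
  }
  bad <- which(bed$start < 0L | bed$start >= bed$end)
  if (length(bad)) {
    abort(sprintf("BED record '%s': requires 0 <= start < end", bed$name[bad[1]]))
  }
  bad <- which(!(bed$chrom %in% names(fasta)))
  if (length(bad)) {
    abort(sprintf("BED record '%s': chrom '%s' not in FASTA",
                  bed$name[bad[1]], bed$chrom[bad[1]]))
  }
  chrom_len <- nchar(fasta)[bed$chrom]
  bad <- which(bed$end > chrom_len)
  if (length(bad)) {
    abort(sprintf("BED record '%s': interval exceeds chromosome bounds",
                  bed$name[bad[1]]))
  }
  seq <- substring(fasta[bed$chrom], bed$start + 1L, bed$end)
  minus <- bed$strand == "-"
  if (any(minus)) seq[minus] <- revcomp(seq[minus])
  tibble(
    name = bed$name, chrom = bed$chrom, start = bed$start, end = bed$end,
    strand = bed$strand, seq = unname(seq), len = bed$end - bed$start,
    gene_id = NA_character_, upstream_exon_len = NA_integer_,
    downstream_exon_len = NA_integer_, transcript_len = NA_integer_
  )
}

#' Write an intron tibble back to BED6
#'
#' Inverse of [read_bed_introns()] for the coordinate columns; sequence and
#' metadata columns are dropped. Round-trips coordinates bit-exactly.
#'
#' @param introns tibble with `chrom`, `start`, `end`, `name`, `strand`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bed_introns <- function(introns, path) {
  stopifnot(all(c("chrom", "start", "end", "name", "strand") %in% names(introns)))
  readr::write_tsv(
    tibble(chrom = introns$chrom, start = introns$start, end = introns$end,
           name = introns$name, score = 0, strand = introns$strand),
    path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Extract the 3'-terminal region of intron sequences
#'
#' Position convention throughout the package: -1 is the last intron
#' nucleotide (the G of the terminal AG), -2 the A, and so on 5'-wards.
#' The 3' `n` nucleotides are therefore positions -n..-1.
#'
#' @param seq character vector of sense-strand intron sequences.
#' @param n region width in nucleotides (>= 1).
#' @return character vector of suffixes of length `min(n, nchar(seq))`, with
#'   a logical attribute `truncated` marking introns shorter than `n`.
#' @examples
#' three_prime_region("TTTACTAACAG", 5)
#' @export
three_prime_region <- function(seq, n) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  seq <- norm_seq(seq)
  len <- nchar(seq)
  k <- pmin(as.integer(n), len)
  out <- substring(seq, len - k + 1L, len)
  attr(out, "truncated") <- len < n
  out
}
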