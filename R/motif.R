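# IUPAC degenerate nucleotide classes; U is normalised to T upstream.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Find all matches of a degenerate IUPAC pattern
#'
#' Scans every window (overlaps included) of `seq` and reports the windows
#' where each position satisfies its IUPAC class. An `N` in the sequence
#' never matches any pattern symbol, including pattern `N` — ambiguous
#' bases are treated conservatively as non-evidence.
#'
#' @param seq a single nucleotide string (A, C, G, T, U, N).
#' @param pattern IUPAC pattern, e.g. `"YNYYRAY"` for the branch-point
#'   consensus or `"YUNAY"`.
#' @return integer vector of 0-based match offsets (possibly empty).
#' @examples
#' match_degenerate("TACTAACTACTAAC", "YNYYRAY")
#' @export
match_degenerate <- function(seq, pattern) {
  stopifnot(is.character(seq), length(seq) == 1L,
            is.character(pattern), length(pattern) == 1L)
  seq <- norm_seq(seq)
  pattern <- chartr("u", "U", toupper(pattern))
  pat <- seq_chars(pattern)
  unknown <- setdiff(pat, names(IUPAC_SETS))
  if (length(unknown)) {
    abort(sprintf("unknown IUPAC code in pattern: %s", unknown[1]))
  }
  m <- length(pat)
  n <- nchar(seq)
  if (m == 0L) abort("pattern must be non-empty")
  if (n < m) return(integer(0))
  chars <- seq_chars(seq)
  n_win <- n - m + 1L
  ok <- rep(TRUE, n_win)
  for (j in seq_len(m)) {
    ok <- ok & (chars[j:(j + n_win - 1L)] %in% IUPAC_SETS[[pat[j]]])
  }
  which(ok) - 1L
}

#' Count branch-point consensus matches near the 3' splice site
#'
#' Counts degenerate matches of `pattern` within the 3'-terminal `window`
#' nucleotides of each intron. Events with exactly one match form the
#' single-BP class; two or more, the multi-BP class; zero matches are
#' reported as their own class — additional BP-like sequences 5' of the
#' main branch point attenuate drug response.
#'
#' @param introns tibble with a `seq` column (sense strand), or a character
#'   vector of intron sequences.
#' @param pattern IUPAC branch-point consensus (default `"YNYYRAY"`).
#' @param window width of the 3' window scanned, in nucleotides.
#' @return the input tibble with columns `n_bp_matches` (integer) and
#'   `bp_class` (factor: `"0"`, `"1 BP"`, `"BPs"`); for a character input,
#'   an integer vector of counts.
#' @export
count_bp_matches <- function(introns, pattern = "YNYYRAY", window = 100L) {
  stopifnot(window >= nchar(pattern))
  seqs <- if (is.data.frame(introns)) introns$seq else introns
  region <- three_prime_region(seqs, window)
  counts <- vapply(region, function(r) length(match_degenerate(r, pattern)),
                   integer(1), USE.NAMES = FALSE)
  if (!is.data.frame(introns)) return(counts)
  introns |>
    mutate(
      n_bp_matches = counts,
      bp_class = factor(
        dplyr::case_when(counts == 0L ~ "0", counts == 1L ~ "1 BP", TRUE ~ "BPs"),
        levels = c("0", "1 BP", "BPs")))
}
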