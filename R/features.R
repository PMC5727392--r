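#' Score a branch-point heptamer for base pairing with U2 snRNA
#'
#' The branch-point region pairs with the GUAGUA recognition register of U2
#' snRNA, with the branch adenosine (heptamer position 6) bulged out and
#' therefore unscored. The optimal heptamer TACTAAC pairs perfectly. Each
#' of the six paired positions contributes +1.0 for the Watson-Crick
#' partner, +0.5 for a G:U wobble (G opposite a U2 uridine at positions 2
#' and 5; T opposite a U2 guanosine at positions 3 and 7) and 0 otherwise;
#' N scores 0.
#'
#' @param heptamer character vector of 7-nt sequences (A, C, G, T, N).
#' @return numeric vector of scores in \[0, 6\]; 6.0 iff the heptamer is
#'   TACTAAC.
#' @examples
#' u2_pairing_score(c("TACTAAC", "CTCTCAC"))
#' @export
u2_pairing_score <- function(heptamer) {
  heptamer <- norm_seq(heptamer, what = "heptamer")
  if (any(nchar(heptamer) != 7L)) {
    abort("u2_pairing_score() requires heptamers of length exactly 7")
  }
  # Watson-Crick partner and wobble-scoring base per heptamer position;
  # position 6 (the branch nucleotide) is bulged and unscored.
  wc  <- c("T", "A", "C", "T", "A", NA, "C")
  wob <- c(NA, "G", "T", NA, "G", NA, "T")
  score <- numeric(length(heptamer))
  for (j in c(1L:5L, 7L)) {
    b <- substr(heptamer, j, j)
    score <- score + (b == wc[j]) + 0.5 * (!is.na(wob[j]) & b == wob[j])
  }
  score
}

# log2-odds lookup (width x 5, last column N -> 0) for fast scanning
pwm_logodds <- function(x) {
  stopifnot(inherits(x, "bs_pwm"))
  lo <- log2(sweep(x$probs, 2, x$background, "/"))
  cbind(lo, N = 0)
}

# sum of per-position log2-odds for sequences of length exactly pwm width
pwm_score_exact <- function(seqs, x) {
  lo <- pwm_logodds(x)
  score <- numeric(length(seqs))
  for (j in seq_len(x$width)) {
    score <- score + lo[j, match(substr(seqs, j, j), colnames(lo))]
  }
  unname(score)
}

#' Maximal PWM binding score over all windows of a sequence
#'
#' Scans every window of `seq` with the PWM and returns the maximum sum of
#' per-base log2 odds against the background. Ties are broken toward the
#' 3'-most window. N positions contribute 0 (background odds). Used with
#' [sf1_pwm()] this is the SF1 binding score of an intron 3' end.
#'
#' @param seq a single nucleotide string, at least as long as the PWM.
#' @param pwm a `bs_pwm` object.
#' @return list with `score` (float) and `offset` (0-based start of the
#'   best window).
#' @export
pwm_max_score <- function(seq, pwm) {
  stopifnot(is.character(seq), length(seq) == 1L, inherits(pwm, "bs_pwm"))
  seq <- norm_seq(seq)
  n <- nchar(seq)
  if (n < pwm$width) {
    abort(sprintf("sequence (length %d) shorter than PWM width %d", n, pwm$width))
  }
  lo <- pwm_logodds(pwm)
  chars <- seq_chars(seq)
  n_win <- n - pwm$width + 1L
  scores <- numeric(n_win)
  for (j in seq_len(pwm$width)) {
    scores <- scores + lo[j, match(chars[j:(j + n_win - 1L)], colnames(lo))]
  }
  best <- max(scores)
  list(score = unname(best), offset = max(which(scores >= best - 1e-12)) - 1L)
}

# per-base polypyrimidine weights; N is treated like the most disruptive
# base so ambiguous stretches never inflate tract strength
PPT_WEIGHTS <- c(T = 1.0, C = 0.5, A = -1.5, G = -2.0, N = -2.0)

#' Score the polypyrimidine tract of a region
#'
#' Finds the maximum-sum contiguous segment under per-base weights
#' T = +1.0, C = +0.5, A = -1.5, G = -2.0, so T-rich tracts outscore C-rich
#' tracts of equal length and purines interrupt. The empty segment is
#' allowed (score 0, length 0). Ties are broken toward the segment closest
#' to the 3' end (largest end, then shortest).
#'
#' @param region a single nucleotide string (typically branch point to -3).
#' @return list with `score`, `length` (nt) and `offset` (0-based segment
#'   start, NA when the best segment is empty).
#' @examples
#' ppt_score("TTAGTTTT")
#' @export
ppt_score <- function(region) {
  stopifnot(is.character(region), length(region) == 1L)
  region <- norm_seq(region)
  if (nchar(region) == 0L) abort("ppt_score() requires a non-empty region")
  w <- unname(PPT_WEIGHTS[seq_chars(region)])
  cs <- c(0, cumsum(w))
  n <- length(w)
  # best segment ending at j: cs[j+1] - min(cs[1..j]); prefer the latest
  # qualifying start (shortest segment) and then the latest end
  pre_min <- cummin(cs[seq_len(n)])
  ends <- cs[-1] - pre_min
  best <- max(0, ends)
  if (best <= 0) return(list(score = 0, length = 0L, offset = NA_integer_))
  j <- max(which(ends >= best - 1e-12))
  i <- max(which(cs[seq_len(j)] <= pre_min[j] + 1e-12))
  list(score = unname(best), length = j - i + 1L, offset = i - 1L)
}

#' GC content of nucleotide sequences
#'
#' Fraction (G + C) / (A + C + G + T); N is excluded from both numerator
#' and denominator. All-N (or empty) sequences return NA.
#'
#' @param seq character vector of nucleotide sequences.
#' @return numeric vector of fractions in \[0, 1\] (or NA).
#' @export
gc_content <- function(seq) {
  seq <- norm_seq(seq)
  counts <- vapply(c("G", "C", "A", "T"), function(b) {
    nchar(seq) - nchar(gsub(b, "", seq, fixed = TRUE))
  }, numeric(length(seq)))
  counts <- matrix(counts, ncol = 4L)
  denom <- rowSums(counts)
  ifelse(denom > 0, (counts[, 1] + counts[, 2]) / denom, NA_real_)
}

#' Enumerate branch-point candidates of one intron
#'
#' Every heptamer whose putative branch nucleotide (position 6) lies within
#' the 3' `bp_window` and at least 3 nt from the intron end is a candidate.
#' Candidates with an adenosine at position 6 are functional; those without
#' are retained as decoys (able to pair with U2 snRNA but splicing-inactive)
#' for reporting, and are never chosen as the best functional BP.
#'
#' @param seq a single sense-strand intron sequence (>= 7 nt).
#' @param pwm a `bs_pwm` used for the per-candidate binding score.
#' @param bp_window 3' window (nt) in which branch nucleotides are sought.
#' @return tibble with columns `offset` (heptamer start, -1 = last intron
#'   nt), `branch_offset` (= offset + 5), `heptamer`, `functional`,
#'   `pairing_score`, `pwm_score`, `matches_ynyyray`, `matches_yunay`.
#' @export
bp_candidates <- function(seq, pwm = sf1_pwm(), bp_window = 150L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- norm_seq(seq)
  len <- nchar(seq)
  if (len < 7L) abort("intron shorter than 7 nt has no branch-point candidates")
  b_lo <- max(-as.integer(bp_window), -len + 5L)
  b_hi <- -4L
  if (b_lo > b_hi) {
    return(tibble(offset = integer(), branch_offset = integer(),
                  heptamer = character(), functional = logical(),
                  pairing_score = numeric(), pwm_score = numeric(),
                  matches_ynyyray = logical(), matches_yunay = logical()))
  }
  branch <- seq(b_lo, b_hi)
  offset <- branch - 5L
  start_idx <- len + offset + 1L
  heptamer <- substring(seq, start_idx, start_idx + 6L)
  ynyyray <- vapply(heptamer, function(h) length(match_degenerate(h, "YNYYRAY")) > 0,
                    logical(1), USE.NAMES = FALSE)
  yunay <- vapply(heptamer, function(h) length(match_degenerate(h, "YUNAY")) > 0,
                  logical(1), USE.NAMES = FALSE)
  tibble(
    offset = offset, branch_offset = branch, heptamer = heptamer,
    functional = substr(heptamer, 6L, 6L) == "A",
    pairing_score = u2_pairing_score(heptamer),
    pwm_score = if (pwm$width == 7L) pwm_score_exact(heptamer, pwm) else NA_real_,
    matches_ynyyray = ynyyray, matches_yunay = yunay)
}

# feature vector of one intron; exon_seq / exon_len / transcript_len optional
score_one_intron <- function(seq, pwm, bp_window, multi_bp_window,
                             exon_seq = NA_character_, exon_len = NA_integer_,
                             transcript_len = NA_integer_) {
  len <- nchar(seq)
  if (len < 7L) abort("score_introns() requires introns of length >= 7")
  cand <- bp_candidates(seq, pwm = pwm, bp_window = bp_window)
  fun <- cand[cand$functional, , drop = FALSE]
  if (nrow(fun) > 0L) {
    # best functional BP: max pairing, then max PWM, then 3'-most
    ord <- order(-fun$pairing_score, -fun$pwm_score, -fun$branch_offset)
    best <- fun[ord[1], ]
    bp_pairing <- best$pairing_score
    bp_distance <- abs(best$branch_offset)
    # polypyrimidine tract between the BP heptamer and position -3
    # (the heptamer's own 3' base and the terminal AG are excluded)
    ppt_from <- len + best$branch_offset + 3L
  } else {
    bp_pairing <- NA_real_
    bp_distance <- NA_integer_
    ppt_from <- max(1L, len - as.integer(bp_window) + 1L)
  }
  ppt_region <- substr(seq, ppt_from, len - 2L)
  ppt <- if (nchar(ppt_region) > 0L) ppt_score(ppt_region) else
    list(score = 0, length = 0L, offset = NA_integer_)
  region <- three_prime_region(seq, bp_window)
  sf1 <- pwm_max_score(region, pwm)
  tibble(
    bp_best_pairing = bp_pairing,
    bp_best_pwm = sf1$score,
    bp_distance = bp_distance,
    n_bp_matches_100 = length(match_degenerate(
      three_prime_region(seq, multi_bp_window), "YNYYRAY")),
    ppt_score = ppt$score,
    ppt_length = ppt$length,
    gc_intron = gc_content(seq),
    gc_exon = if (!is.na(exon_seq)) gc_content(exon_seq) else NA_real_,
    len_intron = len,
    len_exon = as.integer(exon_len),
    len_transcript = as.integer(transcript_len))
}

#' Compute the full 3' splice site feature vector for each intron
#'
#' For every intron: the best functional branch point in the 3'
#' `bp_window` (maximum U2 pairing score; ties broken by PWM score, then
#' toward the 3'-most candidate), its distance from the 3' splice site, the
#' maximal SF1 PWM binding score in the window, the polypyrimidine-tract
#' score between the chosen BP heptamer and position -3 (the
#' terminal AG is excluded), the number of YNYYRAY branch-point consensus
#' matches in the 3' `multi_bp_window`, GC content and lengths.
#'
#' @param introns tibble with a `seq` column (sense strand); optional
#'   columns `name`, `exon_seq`, `exon_len`, `transcript_len` are carried
#'   into the output.
#' @param pwm a `bs_pwm`; defaults to the YNYYRAY-consensus SF1 stand-in.
#' @param bp_window 3' window for BP and SF1 scoring (nt).
#' @param multi_bp_window 3' window for counting BP consensus matches (nt).
#' @return tibble, one row per intron: `name` plus the feature columns
#'   `bp_best_pairing`, `bp_best_pwm`, `bp_distance`, `n_bp_matches_100`,
#'   `ppt_score`, `ppt_length`, `gc_intron`, `gc_exon`, `len_intron`,
#'   `len_exon`, `len_transcript`.
#' @export
score_introns <- function(introns, pwm = sf1_pwm(), bp_window = 150L,
                          multi_bp_window = 100L) {
  if (is.character(introns)) introns <- tibble(seq = introns)
  stopifnot(is.data.frame(introns), "seq" %in% names(introns))
  n <- nrow(introns)
  grab <- function(col, default) {
    if (col %in% names(introns)) introns[[col]] else rep(default, n)
  }
  nm <- grab("name", NA_character_)
  if (all(is.na(nm))) nm <- paste0("intron_", seq_len(n))
  rows <- purrr::pmap(
    list(norm_seq(introns$seq), grab("exon_seq", NA_character_),
         grab("exon_len", NA_integer_), grab("transcript_len", NA_integer_)),
    function(s, es, el, tl) {
      score_one_intron(s, pwm, bp_window, multi_bp_window,
                       exon_seq = es, exon_len = el, transcript_len = tl)
    })
  bind_cols(tibble(name = nm), bind_rows(rows))
}

#' Difference feature vectors of the introns flanking an alternative exon
#'
#' For cassette exons the regulated 3' splice site belongs to the upstream
#' intron, while the downstream intron's 3' splice site is used in both
#' inclusion and skipping; the upstream-minus-downstream difference of the
#' BP and polypyrimidine scores isolates the regulated site.
#'
#' @param upstream,downstream feature tibbles from [score_introns()],
#'   row-aligned by event.
#' @param features columns to difference.
#' @return tibble of `upstream - downstream` for the chosen features (NA
#'   propagates), keeping `name` from `upstream`.
#' @export
flanking_diff <- function(upstream, downstream,
                          features = c("bp_best_pwm", "bp_best_pairing",
                                       "ppt_score")) {
  stopifnot(nrow(upstream) == nrow(downstream),
            all(features %in% names(upstream)),
            all(features %in% names(downstream)))
  out <- purrr::map_dfc(setNames(features, features), function(f) {
    upstream[[f]] - downstream[[f]]
  })
  if ("name" %in% names(upstream)) out <- bind_cols(upstream["name"], out)
  out
}
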