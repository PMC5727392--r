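test_that("U2 pairing score reproduces the enumerated reference heptamers", {
  expect_equal(u2_pairing_score("TACTAAC"), 6.0)
  expect_equal(u2_pairing_score("CTCTCAC"), 3.0)  # positions 3, 4, 7 WC
  expect_equal(u2_pairing_score("TTTTTTT"), 3.0)  # 2 WC + 2 wobbles
  expect_equal(u2_pairing_score("NNNNNNN"), 0.0)
  expect_error(u2_pairing_score("TACTAA"), "length")
})

test_that("TACTAAC is the unique maximal heptamer", {
  withr::local_seed(9)
  hept <- vapply(1:500, function(i) random_dna(7), character(1))
  scores <- u2_pairing_score(hept)
  expect_true(all(scores >= 0 & scores <= 6))
  expect_true(all(scores[hept != "TACTAAC"] < 6))
})

test_that("PWM max score matches hand arithmetic and the brute-force scan", {
  uniform <- pwm(matrix(1, 4, 4))
  withr::local_seed(2)
  expect_equal(pwm_max_score(random_dna(50), uniform)$score, 0)

  eps <- 1e-4
  width1 <- pwm(matrix(c(1, 0, 0, 0), 1, 4), pseudocount = eps)
  res <- pwm_max_score("CAC", width1)
  expect_equal(res$score, log2(((1 + eps) / (1 + 4 * eps)) / 0.25))
  expect_equal(res$offset, 1L)

  p7 <- sf1_pwm()
  for (i in 1:40) {
    s <- random_dna(sample(10:120, 1), p_n = 0.03)
    got <- pwm_max_score(s, p7)
    want <- oracle_pwm_max(s, p7)
    expect_equal(got$score, want$score, tolerance = 1e-9)
    expect_equal(got$offset, want$offset)
  }
  expect_error(pwm_max_score("ACG", p7), "shorter")
})

test_that("PWM max score is non-decreasing under sequence extension", {
  withr::local_seed(14)
  p <- sf1_pwm()
  for (i in 1:20) {
    s <- random_dna(40)
    ext <- paste0(random_dna(10), s, random_dna(10))
    expect_gte(pwm_max_score(ext, p)$score, pwm_max_score(s, p)$score - 1e-12)
  }
})

test_that("PPT scoring matches exhaustive segment enumeration", {
  expect_equal(ppt_score("GGAAGG")[c("score", "length")],
               list(score = 0, length = 0L))
  expect_equal(ppt_score(strrep("T", 10))[c("score", "length")],
               list(score = 10, length = 10L))
  got <- ppt_score("TTAGTTTT")
  expect_equal(got$score, 4.0)
  expect_equal(got$length, 4L)
  expect_equal(got$offset, 4L)  # the 3' TTTT run

  withr::local_seed(19)
  for (i in 1:60) {
    r <- random_dna(sample(2:60, 1), p_n = 0.05)
    expect_equal(ppt_score(r), oracle_ppt(r), label = r)
  }
})

test_that("GC content excludes N and handles edge cases", {
  expect_equal(gc_content(c("GGCC", "AATT", "GANT")), c(1, 0, 1 / 3))
  expect_true(is.na(gc_content("NNNN")))
})

test_that("score_introns recovers a planted optimal branch point", {
  withr::local_seed(42)
  # plant TACTAAC with heptamer start at -30 (branch A at -25), AG terminus
  s <- paste0(random_dna(370), "TACTAAC", strrep("T", 21), "AG")
  feats <- score_introns(tibble::tibble(seq = s))
  expect_equal(feats$bp_best_pairing, 6.0)
  expect_equal(feats$bp_distance, 25L)
  # all pyrimidine tract between branch and -3 is found
  expect_gte(feats$ppt_score, 15)
})

test_that("no pyrimidines downstream of the BP gives a zero PPT score", {
  s <- paste0(strrep("G", 100), "TACTAAC", strrep("A", 18), "AG")
  feats <- score_introns(tibble::tibble(seq = s))
  expect_equal(feats$bp_best_pairing, 6.0)
  expect_equal(feats$ppt_score, 0)
  expect_equal(feats$ppt_length, 0L)
})

test_that("features equal independent recomputation on random introns", {
  withr::local_seed(55)
  n_ok <- 0
  for (i in 1:50) {
    s <- paste0(random_dna(sample(80:400, 1)), "AG")
    feats <- score_introns(tibble::tibble(seq = s))
    len <- nchar(s)
    # independent recomputation from raw string operations
    region <- substr(s, max(1, len - 149), len)
    expect_equal(feats$bp_best_pwm, oracle_pwm_max(region, sf1_pwm())$score,
                 tolerance = 1e-9)
    expect_equal(feats$n_bp_matches_100,
                 length(oracle_match(substr(s, max(1, len - 99), len),
                                     "YNYYRAY")))
    gsub_len <- function(b) len - nchar(gsub(b, "", s, fixed = TRUE))
    expect_equal(feats$gc_intron,
                 (gsub_len("G") + gsub_len("C")) / len)
    expect_equal(feats$len_intron, len)
    if (!is.na(feats$bp_distance)) {
      # chosen branch nucleotide is an A inside the window, >= 3 nt from end
      branch_idx <- len - feats$bp_distance + 1
      expect_identical(substr(s, branch_idx, branch_idx), "A")
      expect_lte(feats$bp_distance, 150)
      expect_gte(feats$bp_distance, 4)
      # PPT recomputed on the stated region (heptamer and AG excluded)
      expect_equal(feats$ppt_score,
                   oracle_ppt(substr(s, branch_idx + 2, len - 2))$score)
      n_ok <- n_ok + 1
    }
  }
  expect_gt(n_ok, 40)  # nearly every random intron has a functional BP
})

test_that("minus-strand introns score identically to their sense sequence", {
  withr::local_seed(70)
  sense <- paste0(random_dna(300), "TACTAAC", random_dna(20), "AG")
  fa <- c(chr1 = revcomp(sense))
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(sprintf("chr1\t0\t%d\tminus\t0\t-", nchar(sense)), bed)
  introns <- read_bed_introns(bed, fa)
  expect_identical(introns$seq, sense)
  expect_equal(score_introns(introns)[-1],
               score_introns(tibble::tibble(seq = sense))[-1])
})

test_that("decoy candidates (no branch A) are never chosen as best BP", {
  # TACTAGC pairs well with U2 but position 6 is not A
  s <- paste0(strrep("G", 80), "TACTAGC", strrep("G", 10), "CTCTCAC",
              strrep("T", 10), "AG")
  cand <- bp_candidates(s)
  decoy <- cand[cand$heptamer == "TACTAGC", ]
  expect_false(any(decoy$functional))
  feats <- score_introns(tibble::tibble(seq = s))
  expect_equal(feats$bp_best_pairing, 3.0)  # CTCTCAC, the functional one
})

test_that("flanking differences are elementwise upstream minus downstream", {
  up <- score_introns(tibble::tibble(
    seq = paste0(strrep("G", 50), "TACTAAC", strrep("T", 15), "AG")))
  down <- score_introns(tibble::tibble(
    seq = paste0(strrep("G", 50), "CTCTCAC", strrep("T", 15), "AG")))
  d <- flanking_diff(up, down)
  expect_equal(d$bp_best_pairing, 6.0 - 3.0)
  expect_equal(flanking_diff(up, up)$bp_best_pairing, 0)
  expect_equal(flanking_diff(up, up)$ppt_score, 0)

  withr::local_seed(3)
  a <- tibble::tibble(bp_best_pwm = rnorm(10), bp_best_pairing = rnorm(10),
                      ppt_score = rnorm(10))
  b <- tibble::tibble(bp_best_pwm = rnorm(10), bp_best_pairing = rnorm(10),
                      ppt_score = rnorm(10))
  expect_equal(flanking_diff(a, b)$ppt_score, a$ppt_score - b$ppt_score)
  a$ppt_score[3] <- NA
  expect_true(is.na(flanking_diff(a, b)$ppt_score[3]))
})
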