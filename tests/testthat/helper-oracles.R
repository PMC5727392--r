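# Independent brute-force oracles used to cross-check the package's scanning
# and scoring code paths. These deliberately re-derive everything from their
# own lookup tables and naive loops.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# naive sliding-window degenerate matcher; N in the sequence never matches
oracle_match <- function(seq, pattern) {
  s <- strsplit(toupper(seq), "")[[1]]
  s[s == "U"] <- "T"
  p <- strsplit(toupper(pattern), "")[[1]]
  m <- length(p)
  n <- length(s)
  hits <- integer(0)
  if (n < m) return(hits)
  for (i in seq_len(n - m + 1)) {
    ok <- TRUE
    for (j in seq_len(m)) {
      if (s[i + j - 1] == "N" || !(s[i + j - 1] %in% ORACLE_IUPAC[[p[j]]])) {
        ok <- FALSE
        break
      }
    }
    if (ok) hits <- c(hits, i - 1L)
  }
  hits
}

# exhaustive maximum-sum segment search over all O(n^2) segments with the
# package's tie rule (max score, then latest end, then latest start);
# the empty segment (score 0) is allowed
oracle_ppt <- function(region) {
  w_tab <- c(T = 1.0, C = 0.5, A = -1.5, G = -2.0, N = -2.0)
  w <- unname(w_tab[strsplit(toupper(region), "")[[1]]])
  n <- length(w)
  cs <- c(0, cumsum(w))
  # segment_sum[i, j] = sum(w[i:j]) for every i <= j
  sums <- outer(cs[seq_len(n)], cs[-1], function(a, b) b - a)
  sums[row(sums) > col(sums)] <- NA
  best_sc <- max(0, sums, na.rm = TRUE)
  if (best_sc <= 1e-12) {
    return(list(score = 0, length = 0L, offset = NA_integer_))
  }
  hits <- which(!is.na(sums) & abs(sums - best_sc) <= 1e-12, arr.ind = TRUE)
  j <- max(hits[, "col"])
  i <- max(hits[hits[, "col"] == j, "row"])
  list(score = best_sc, length = j - i + 1L, offset = i - 1L)
}

# naive windowed log2-odds PWM scan, ties toward the 3'-most window
oracle_pwm_max <- function(seq, pwm_obj) {
  s <- strsplit(toupper(seq), "")[[1]]
  w <- pwm_obj$width
  n <- length(s)
  best <- -Inf
  best_off <- NA_integer_
  for (i in seq_len(n - w + 1)) {
    sc <- 0
    for (j in seq_len(w)) {
      b <- s[i + j - 1]
      sc <- sc + if (b == "N") 0 else
        log2(pwm_obj$probs[j, b] / pwm_obj$background[[b]])
    }
    if (sc >= best - 1e-12) {
      if (sc > best) best <- unname(sc)
      best_off <- i - 1L
    }
  }
  list(score = best, offset = best_off)
}

random_dna <- function(n, p_n = 0) {
  alphabet <- c("A", "C", "G", "T")
  if (p_n > 0) {
    paste0(sample(c(alphabet, "N"), n, replace = TRUE,
                  prob = c(rep((1 - p_n) / 4, 4), p_n)), collapse = "")
  } else {
    paste0(sample(alphabet, n, replace = TRUE), collapse = "")
  }
}

random_iupac_pattern <- function(len) {
  paste0(sample(c("A", "C", "G", "T", "R", "Y", "W", "S", "N"), len,
                replace = TRUE, prob = c(rep(0.15, 4), rep(0.08, 5))),
         collapse = "")
}

# small wide event table fixture builder (2 replicates per condition)
make_event_table <- function(type = c("CE", "IR", "CE"),
                             samples = c("DMSO_1", "DMSO_2",
                                         "SudC1_1", "SudC1_2")) {
  n <- length(type)
  tbl <- tibble::tibble(
    EVENT_ID = paste0("ev", seq_len(n)),
    GENE_ID = paste0("g", seq_len(n)),
    TYPE = type, CHROM = paste0("chr", seq_len(n)), STRAND = "+",
    COORDS = "0-100")
  for (s in samples) {
    tbl[[paste0("INC1_", s)]] <- ifelse(type == "CE", 20L, NA_integer_)
    tbl[[paste0("INC2_", s)]] <- ifelse(type == "CE", 20L, NA_integer_)
    tbl[[paste0("EXC_", s)]] <- ifelse(type == "CE", 5L, NA_integer_)
    tbl[[paste0("EI1_", s)]] <- ifelse(type == "IR", 5L, NA_integer_)
    tbl[[paste0("EI2_", s)]] <- ifelse(type == "IR", 5L, NA_integer_)
    tbl[[paste0("EE_", s)]] <- ifelse(type == "IR", 30L, NA_integer_)
    tbl[[paste0("FPKM_", s)]] <- 10
  }
  tbl
}
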