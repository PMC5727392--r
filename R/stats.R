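#' Significance stars with the figure-legend convention
#'
#' `*` p < 0.01, `**` p < 0.001, `***` p < 0.0001, otherwise `n.s.`.
#'
#' @param p numeric vector of p values.
#' @return character vector of star annotations.
#' @export
p_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 1e-4 ~ "***",
    p < 1e-3 ~ "**",
    p < 1e-2 ~ "*",
    TRUE ~ "n.s.")
}

#' Two-sided Mann-Whitney U test
#'
#' U is the rank-sum statistic for `x` (midranks under ties). The p value
#' is exact (enumeration over arrangements) when `min(n1, n2) <= 8` and
#' there are no ties, otherwise a normal approximation with tie and
#' continuity corrections is used.
#'
#' @param x,y numeric samples.
#' @param feature optional label carried into the output.
#' @return one-row tibble: `feature`, `n1`, `n2`, `median1`, `median2`,
#'   `U`, `p_two_sided`, `direction` (sign of `median1 - median2`),
#'   `stars`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney_u <- function(x, y, feature = NA_character_) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) {
    abort("mann_whitney_u() requires non-empty samples")
  }
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- min(n1, n2) <= 8 && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE))
  tibble(
    feature = feature, n1 = n1, n2 = n2,
    median1 = median(x), median2 = median(y),
    U = unname(u), p_two_sided = wt$p.value,
    direction = sign(median(x) - median(y)),
    stars = p_stars(wt$p.value))
}

#' Pearson chi-square enrichment test on a 2x2 table
#'
#' Compares the regulated fraction of a group against a reference universe
#' (e.g. drug-regulated cassette exons vs all detected cassette exons).
#' No continuity (Yates) correction; df = 1.
#'
#' @param regulated,universe regulated count and universe size of the group.
#' @param regulated_ref,universe_ref the same for the reference.
#' @return one-row tibble: `chi2`, `df`, `p`, `stars`.
#' @export
chi2_2x2 <- function(regulated, universe, regulated_ref, universe_ref) {
  stopifnot(regulated >= 0, regulated_ref >= 0,
            universe > 0, universe_ref > 0,
            regulated <= universe, regulated_ref <= universe_ref)
  tab <- rbind(c(regulated, universe - regulated),
               c(regulated_ref, universe_ref - regulated_ref))
  if (any(colSums(tab) == 0) || any(rowSums(tab) == 0)) {
    abort("chi2_2x2(): a table margin is zero")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble(chi2 = unname(ct$statistic), df = unname(ct$parameter),
         p = ct$p.value, stars = p_stars(ct$p.value))
}

#' Welch two-sided t test on replicate PSI values
#'
#' @param psi_a,psi_b numeric vectors of replicate PSI percentages
#'   (at least 2 each).
#' @return one-row tibble: `t`, `df`, `p_two_sided`, `mean_a`, `mean_b`,
#'   `stars`.
#' @export
t_test_psi <- function(psi_a, psi_b) {
  if (length(psi_a) < 2L || length(psi_b) < 2L) {
    abort("t_test_psi() requires at least 2 replicates per group")
  }
  if (sd(psi_a) == 0 && sd(psi_b) == 0 && psi_a[1] == psi_b[1]) {
    # identical constant groups: no evidence of difference
    return(tibble(t = 0, df = NA_real_, p_two_sided = 1,
                  mean_a = mean(psi_a), mean_b = mean(psi_b), stars = "n.s."))
  }
  tt <- t.test(psi_a, psi_b, var.equal = FALSE)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p_two_sided = tt$p.value, mean_a = mean(psi_a), mean_b = mean(psi_b),
         stars = p_stars(tt$p.value))
}

#' Correlation between splicing change magnitude and gene expression
#'
#' Pearson R between `|delta|` and `log10(FPKM + 1)` (the log transform is
#' the default because FPKM is heavy-tailed; set `log_fpkm = FALSE` for raw
#' values). Used to test whether drug-induced splicing changes track
#' transcription levels.
#'
#' @param abs_delta absolute delta-PSI/PIR percentages.
#' @param fpkm per-event host-gene FPKM values.
#' @param log_fpkm correlate against `log10(FPKM + 1)`?
#' @return one-row tibble: `r`, `p`, `n` (`r` is NA when either variable
#'   has zero variance).
#' @export
expr_splicing_correlation <- function(abs_delta, fpkm, log_fpkm = TRUE) {
  keep <- !is.na(abs_delta) & !is.na(fpkm)
  a <- abs_delta[keep]
  f <- if (log_fpkm) log10(fpkm[keep] + 1) else fpkm[keep]
  if (length(a) < 3L) abort("expr_splicing_correlation() requires n >= 3 pairs")
  if (sd(a) == 0 || sd(f) == 0) {
    return(tibble(r = NA_real_, p = NA_real_, n = length(a)))
  }
  ct <- cor.test(a, f, method = "pearson")
  tibble(r = unname(ct$estimate), p = ct$p.value, n = length(a))
}

#' Venn-partition counts and pairwise sharing between drug target sets
#'
#' @param sets named list (>= 2) of character vectors (event ids).
#' @return list with `regions` (tibble: `region` = `+`-joined member set
#'   names, `count` of elements exclusive to that intersection) and
#'   `shared` (tibble: `from`, `to`, `n_common`, `pct_of_from` =
#'   `100 * |from ∩ to| / |from|`).
#' @export
overlap_matrix <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2, !is.null(names(sets)))
  sets <- lapply(sets, unique)
  nm <- names(sets)
  k <- length(sets)
  elements <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) elements %in% s, logical(length(elements)))
  membership <- matrix(membership, ncol = k, dimnames = list(NULL, nm))
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  regions <- purrr::map_dfr(seq_len(nrow(patterns)), function(i) {
    pat <- as.logical(patterns[i, ])
    inside <- rowSums(membership[, pat, drop = FALSE]) == sum(pat) &
      rowSums(membership[, !pat, drop = FALSE]) == 0
    tibble(region = paste(nm[pat], collapse = "+"), count = sum(inside))
  })
  shared <- purrr::map_dfr(nm, function(a) purrr::map_dfr(nm, function(b) {
    if (a == b) return(NULL)
    n_common <- length(intersect(sets[[a]], sets[[b]]))
    tibble(from = a, to = b, n_common = n_common,
           pct_of_from = if (length(sets[[a]]) > 0)
             100 * n_common / length(sets[[a]]) else NA_real_)
  }))
  list(regions = regions, shared = shared)
}

# centered moving average with partial windows at the boundaries
smooth_profile <- function(v, window) {
  if (window <= 1L) return(v)
  half <- (window - 1L) %/% 2L
  n <- length(v)
  vapply(seq_len(n), function(i) {
    mean(v[max(1L, i - half):min(n, i + half)], na.rm = TRUE)
  }, numeric(1))
}

#' Positional motif profile (RNA map) around the 3' splice site
#'
#' For each group of 3'-region sequences (right-aligned on the 3' splice
#' site), computes at every position -width..-1 the fraction of sequences
#' in which a degenerate match of `pattern` covers that position, then a
#' centered moving average of width `smooth`. Sequences shorter than
#' `width` contribute only where they are defined.
#'
#' @param groups named list of character vectors of sequences (each
#'   >= 7 nt, non-empty groups).
#' @param pattern IUPAC motif, e.g. `"YNYYRAY"`.
#' @param width profile width in nt (positions -width..-1).
#' @param smooth moving-average window in nt (1 = none).
#' @return a tibble of class `bs_rna_map`: `position`, `group`,
#'   `coverage` (raw fraction), `smoothed`, `n` (sequences defined at the
#'   position).
#' @export
rna_map <- function(groups, pattern = "YNYYRAY", width = 150L, smooth = 15L) {
  stopifnot(is.list(groups), !is.null(names(groups)), length(groups) >= 1)
  if (any(lengths(groups) == 0L)) {
    abort(sprintf("rna_map(): group '%s' is empty",
                  names(groups)[lengths(groups) == 0L][1]))
  }
  out <- purrr::imap_dfr(groups, function(seqs, gname) {
    seqs <- three_prime_region(norm_seq(seqs), width)
    cover <- matrix(NA_real_, nrow = length(seqs), ncol = width)
    for (i in seq_along(seqs)) {
      len <- nchar(seqs[i])
      first_col <- width - len + 1L
      cover[i, first_col:width] <- 0
      hits <- match_degenerate(seqs[i], pattern)
      for (h in hits) {
        cols <- (first_col + h):(first_col + h + nchar(pattern) - 1L)
        cover[i, cols] <- 1
      }
    }
    frac <- colMeans(cover, na.rm = TRUE)
    n_def <- colSums(!is.na(cover))
    frac[n_def == 0L] <- NA_real_
    tibble(position = seq(-width, -1L), group = gname, coverage = frac,
           smoothed = smooth_profile(frac, smooth), n = n_def)
  })
  class(out) <- c("bs_rna_map", class(out))
  out
}

#' Hierarchical ordering of a delta matrix for heatmaps
#'
#' Agglomerative clustering (Euclidean distance, complete linkage) of
#' events and of conditions. Rows containing missing values are dropped
#' and reported. Fewer than 2 complete rows returns the identity order.
#'
#' @param delta_matrix numeric matrix, events x conditions, of delta
#'   percentages (rownames = event ids).
#' @return list with `row_order`, `col_order` (integer indices into the
#'   kept matrix), `row_hclust`, `col_hclust` (or NULL), `kept` (row
#'   indices of the input retained), `dropped` (row indices removed for
#'   missing values).
#' @export
heatmap_order <- function(delta_matrix) {
  m <- as.matrix(delta_matrix)
  keep <- which(complete.cases(m))
  dropped <- setdiff(seq_len(nrow(m)), keep)
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < 2L) {
    return(list(row_order = seq_len(nrow(m)), col_order = seq_len(ncol(m)),
                row_hclust = NULL, col_hclust = NULL,
                kept = keep, dropped = dropped))
  }
  rh <- hclust(dist(m, method = "euclidean"), method = "complete")
  ch <- if (ncol(m) >= 2L) {
    hclust(dist(t(m), method = "euclidean"), method = "complete")
  }
  list(row_order = rh$order,
       col_order = if (is.null(ch)) seq_len(ncol(m)) else ch$order,
       row_hclust = rh, col_hclust = ch, kept = keep, dropped = dropped)
}

#' Tukey boxplot summary
#'
#' Quartiles by linear interpolation (`stats::quantile` type 7); whiskers
#' extend to the most extreme data point within 1.5 IQR of the box;
#' points beyond are listed as outliers (they are excluded from plots,
#' never from tests).
#'
#' @param values numeric vector (n >= 1).
#' @return list: `median`, `q1`, `q3`, `whisker_lo`, `whisker_hi`,
#'   `outliers`.
#' @export
summarize_boxplot <- function(values) {
  values <- values[!is.na(values)]
  stopifnot(length(values) >= 1)
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_lo = min(values[inside]), whisker_hi = max(values[inside]),
       outliers = sort(values[!inside]))
}

#' Compare sequence features between two event groups
#'
#' Runs a two-sided Mann-Whitney U test per feature column between the
#' rows of `data` whose `group_col` equals `group_a` and those equal to
#' `group_b`, reproducing the regulated-vs-non-differential feature
#' comparisons (BP scores, PPT score, GC, lengths).
#'
#' @param data tibble holding feature columns and a grouping column.
#' @param group_col name of the grouping column.
#' @param group_a,group_b the two group labels to compare.
#' @param features character vector of feature column names; defaults to
#'   all numeric columns except the grouping column.
#' @return tibble of Mann-Whitney results, one row per feature, with star
#'   annotations.
#' @export
compare_features <- function(data, group_col, group_a, group_b,
                             features = NULL) {
  stopifnot(is.data.frame(data), group_col %in% names(data))
  g <- data[[group_col]]
  if (is.null(features)) {
    features <- names(data)[vapply(data, is.numeric, logical(1))]
    features <- setdiff(features, group_col)
  }
  purrr::map_dfr(features, function(f) {
    x <- data[[f]][g == group_a]
    y <- data[[f]][g == group_b]
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    if (length(x) == 0L || length(y) == 0L) {
      return(tibble(feature = f, n1 = length(x), n2 = length(y),
                    median1 = NA_real_, median2 = NA_real_, U = NA_real_,
                    p_two_sided = NA_real_, direction = NA_real_,
                    stars = NA_character_))
    }
    mann_whitney_u(x, y, feature = f)
  })
}
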