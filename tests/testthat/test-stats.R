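test_that("Mann-Whitney U matches the exact small-sample enumeration", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p_two_sided, 0.1)  # 2 of the 20 arrangements are as extreme

  same <- mann_whitney_u(c(5, 1, 9, 3), c(5, 1, 9, 3))
  expect_equal(same$p_two_sided, 1.0, tolerance = 0.05)
  expect_equal(same$direction, 0)

  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("U statistics of the two orderings sum to n1*n2 without ties", {
  withr::local_seed(12)
  for (i in 1:20) {
    x <- sample(1:1000, sample(3:15, 1))
    y <- sample(1001:2000, sample(3:15, 1)) + 0.5
    u1 <- mann_whitney_u(x, y)$U
    u2 <- mann_whitney_u(y, x)$U
    expect_equal(u1 + u2, length(x) * length(y))
  }
})

test_that("normal approximation tracks the exact p value at moderate n", {
  withr::local_seed(23)
  for (i in 1:40) {
    x <- runif(8)
    y <- runif(sample(8:20, 1))
    p_pkg <- mann_whitney_u(x, y)$p_two_sided
    p_exact <- wilcox.test(x, y, exact = TRUE)$p.value
    expect_lt(abs(p_pkg - p_exact), 0.011)
  }
})

test_that("chi-square matches the 2x2 closed form and its invariances", {
  res <- chi2_2x2(10, 100, 30, 100)
  expect_equal(res$chi2, 12.5)  # n(ad-bc)^2 / product of margins
  expect_equal(res$df, 1L)

  expect_equal(chi2_2x2(20, 100, 20, 100)$chi2, 0)
  # doubling all cells doubles the statistic
  expect_equal(chi2_2x2(20, 200, 60, 200)$chi2, 2 * res$chi2)
  # swapping the two groups leaves the statistic unchanged
  expect_equal(chi2_2x2(30, 100, 10, 100)$chi2, res$chi2)
  expect_error(chi2_2x2(0, 10, 0, 10), "margin")
})

test_that("Welch t test matches hand arithmetic on the 2-point fixture", {
  a <- c(10, 12)
  b <- c(40, 42)
  res <- t_test_psi(a, b)
  # closed form: means 11 vs 41, each var 2 with n 2 -> se = sqrt(2), df = 2
  expect_equal(res$t, (11 - 41) / sqrt(2))
  expect_equal(res$df, 2)
  expect_equal(res$p_two_sided, 2 * pt((11 - 41) / sqrt(2), df = 2))

  swapped <- t_test_psi(b, a)
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$p_two_sided, res$p_two_sided)

  expect_equal(t_test_psi(c(50, 50), c(50, 50))$p_two_sided, 1)
  expect_error(t_test_psi(1, c(2, 3)), "replicates")
})

test_that("expression-splicing correlation handles the canonical fixtures", {
  x <- c(1, 2, 3, 4, 5)
  fpkm <- 10^x - 1  # log10(fpkm + 1) is exactly linear in x
  expect_equal(expr_splicing_correlation(x, fpkm)$r, 1)
  expect_equal(expr_splicing_correlation(rev(x), fpkm)$r, -1)
  expect_true(is.na(expr_splicing_correlation(rep(2, 5), fpkm)$r))
  expect_error(expr_splicing_correlation(1:2, 1:2), "n >= 3")
})

test_that("overlap regions match brute-force set algebra", {
  a <- c("1", "2")
  b <- c("2", "3")
  ov <- overlap_matrix(list(A = a, B = b))
  expect_equal(ov$shared$pct_of_from[ov$shared$from == "A" & ov$shared$to == "B"], 50)
  ov0 <- overlap_matrix(list(A = c("1", "2"), B = c("3", "4")))
  expect_true(all(ov0$shared$pct_of_from == 0))

  sets <- list(X = c("a", "b", "c", "d"), Y = c("c", "d", "e"),
               Z = c("d", "e", "f", "g"))
  ov3 <- overlap_matrix(sets)
  regions <- setNames(ov3$regions$count, ov3$regions$region)
  # brute force over the 7 Venn regions
  all_el <- unique(unlist(sets))
  member <- sapply(sets, function(s) all_el %in% s)
  key <- apply(member, 1, function(m) paste(names(sets)[m], collapse = "+"))
  want <- table(key)
  for (r in names(regions)) {
    expect_equal(unname(regions[[r]]),
                 if (r %in% names(want)) unname(want[[r]]) else 0L,
                 label = r)
  }
})

test_that("RNA maps place coverage where matches are and stay in [0,1]", {
  none <- rna_map(list(g = c("GGGGGGGGGG")), pattern = "YNYYRAY",
                  width = 20, smooth = 1)
  expect_true(all(none$coverage[!is.na(none$coverage)] == 0))

  # one sequence with one TACTAAC match at offsets -10..-4
  s <- paste0("GGG", "TACTAAC", "GGG")
  prof <- rna_map(list(g = s), pattern = "TACTAAC", width = 13, smooth = 1)
  covered <- prof$position[!is.na(prof$coverage) & prof$coverage == 1]
  expect_equal(covered, seq(-10, -4))
  expect_true(all(prof$coverage >= 0 & prof$coverage <= 1, na.rm = TRUE))

  expect_error(rna_map(list(g = character(0))), "empty")
})

test_that("RNA map smoothing preserves mean coverage away from edges", {
  withr::local_seed(31)
  seqs <- vapply(1:50, function(i) random_dna(150), character(1))
  prof <- rna_map(list(g = seqs), pattern = "YNYYRAY", width = 150, smooth = 15)
  inner <- prof$position > -140 & prof$position < -10
  expect_lt(abs(mean(prof$smoothed[inner]) - mean(prof$coverage[inner])), 0.02)
  # planted enrichment is visible against a background group
  enriched <- vapply(1:50, function(i) {
    s <- strsplit(random_dna(150), "")[[1]]
    s[121:127] <- strsplit("TACTAAC", "")[[1]]  # positions -30..-24
    paste0(s, collapse = "")
  }, character(1))
  prof2 <- rna_map(list(bg = seqs, enr = enriched), pattern = "YNYYRAY",
                   width = 150, smooth = 5)
  at <- prof2$position >= -30 & prof2$position <= -24
  expect_gt(mean(prof2$smoothed[at & prof2$group == "enr"]),
            mean(prof2$smoothed[at & prof2$group == "bg"]) + 0.3)
})

test_that("heatmap ordering clusters identical rows first and is stable", {
  m <- rbind(a = c(10, 20, 30), b = c(10, 20, 30), c = c(-50, 0, 50))
  ord <- heatmap_order(m)
  first_merge <- ord$row_hclust$merge[1, ]
  expect_setequal(-first_merge, c(1, 2))  # the identical pair merges first

  # known distances: d(a,b)=0, d(a,c)=sqrt(60^2+20^2+20^2)
  expect_equal(ord$row_hclust$height[1], 0)
  expect_equal(ord$row_hclust$height[2], sqrt(60^2 + 20^2 + 20^2))

  # permutation invariance of the tree heights
  perm <- m[c(3, 1, 2), ]
  expect_equal(sort(heatmap_order(perm)$row_hclust$height),
               sort(ord$row_hclust$height))

  # rows with missing values are dropped and reported
  m2 <- rbind(m, d = c(NA, 1, 2))
  expect_equal(heatmap_order(m2)$dropped, 4L)
  expect_equal(heatmap_order(m[1, , drop = FALSE])$row_order, 1L)
})

test_that("boxplot summaries follow the Tukey definition", {
  const <- summarize_boxplot(rep(7, 10))
  expect_equal(const$q1, 7)
  expect_equal(const$q3, 7)
  expect_length(const$outliers, 0)

  s <- summarize_boxplot(1:100)
  expect_equal(s$q1, unname(quantile(1:100, 0.25)))  # linear interpolation
  expect_equal(s$q3, unname(quantile(1:100, 0.75)))
  expect_equal(s$median, 50.5)
  expect_equal(s$whisker_lo, 1)
  expect_equal(s$whisker_hi, 100)

  with_out <- summarize_boxplot(c(1:10, 100))
  expect_equal(with_out$outliers, 100)
  expect_equal(with_out$whisker_hi, 10)
  single <- summarize_boxplot(5)
  expect_equal(single$median, 5)
})

test_that("significance stars follow the legend convention", {
  expect_equal(p_stars(c(0.5, 0.009, 0.0009, 0.00009, NA)),
               c("n.s.", "*", "**", "***", NA))
})
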