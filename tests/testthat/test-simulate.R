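small_params <- function(...) {
  do.call(sim_params,
          utils::modifyList(list(n_events = 50L, seed = 17L), list(...)))
}

test_that("generation is byte-identical under a fixed seed", {
  a <- generate_event_set(small_params())
  b <- generate_event_set(small_params())
  expect_identical(a$introns, b$introns)
  expect_identical(a$events, b$events)
  expect_identical(a$truth, b$truth)
  # a different seed changes the sequences
  c <- generate_event_set(small_params(seed = 18L))
  expect_false(identical(a$introns$seq, c$introns$seq))
})

test_that("planted TACTAAC branch points are recovered by scoring", {
  p <- sim_params(n_events = 8L, bp_pool = "TACTAAC", extra_bp_prob = 0,
                  seed = 3L)
  gen <- generate_introns(p)
  feats <- score_introns(gen$introns)
  expect_equal(feats$bp_best_pairing, rep(6, 8))
  expect_equal(feats$bp_distance, abs(gen$truth$branch_offset))
})

test_that("planted extra BP consensus matches raise the 3' window count", {
  p_multi <- sim_params(n_events = 40L, extra_bp_prob = 1, seed = 5L)
  p_single <- sim_params(n_events = 40L, extra_bp_prob = 0, seed = 5L)
  n_multi <- count_bp_matches(generate_introns(p_multi)$introns)$n_bp_matches
  n_single <- count_bp_matches(generate_introns(p_single)$introns)$n_bp_matches
  expect_gt(mean(n_multi), mean(n_single))
  expect_true(all(n_multi >= 1))
})

test_that("realized GC tracks the drawn target on long introns", {
  gen <- generate_introns(sim_params(n_events = 60L, seed = 29L))
  long <- gen$introns$len >= 1000
  expect_gt(sum(long), 10)
  realized <- gc_content(gen$introns$seq[long])
  expect_true(all(abs(realized - gen$truth$gc_target[long]) < 0.06))
})

test_that("intron lengths respect the truncation bounds", {
  gen <- generate_introns(sim_params(n_events = 200L, seed = 31L))
  expect_true(all(gen$introns$len >= 70 & gen$introns$len <= 100000))
  expect_true(all(substr(gen$introns$seq, gen$introns$len - 1,
                         gen$introns$len) == "AG"))
})

test_that("the logistic response model has the stated limits", {
  f <- tibble::tibble(z_bp = 0, z_ppt = 0, z_len = 0, z_gc = 0, multi = 0)
  beta0 <- c(b0 = 0, bp = 0, ppt = 0, len = 0, gc = 0, multi = 0)
  expect_equal(true_response(f, beta0, delta_max = 60), 30)  # logistic(0)/2

  beta_m <- c(b0 = 0, bp = 0, ppt = 0, len = 0, gc = 0, multi = 1e6)
  f_multi <- dplyr::mutate(f, multi = 1)
  expect_lt(true_response(f_multi, beta_m, delta_max = 60), 1e-6)

  # monotone decreasing in z_bp when beta_bp > 0
  beta_bp <- c(b0 = 0, bp = 1, ppt = 0, len = 0, gc = 0, multi = 0)
  grid <- tibble::tibble(z_bp = seq(-3, 3, by = 0.5), z_ppt = 0, z_len = 0,
                         z_gc = 0, multi = 0)
  resp <- true_response(grid, beta_bp, delta_max = 60)
  expect_true(all(diff(resp) < 0))

  # CE events respond with a negative sign
  expect_lt(true_response(f, beta0, delta_max = 60, type = "CE"), 0)
})

test_that("event counts are consistent with the planted PSI", {
  sim <- generate_event_set(sim_params(n_events = 300L, seed = 41L,
                                       coverage_mean = 200))
  q <- quantify_events(sim$events, "DMSO", "SudC1", min_reads = 0)
  # high coverage: measured control PSI close to planted truth; delta is
  # noisier (per-junction coverage varies) but tracks the planted change
  delta_true <- sim$truth$psi_treated_true - sim$truth$psi_control_true
  expect_lt(median(abs(q$psi_control - sim$truth$psi_control_true)), 2)
  expect_lt(median(abs(q$delta - delta_true)), 6)
  expect_gt(cor(q$delta, delta_true), 0.9)
})

test_that("ridge keeps separable toy data finite and both fits recover signs", {
  withr::local_seed(61)
  n <- 400
  f <- tibble::tibble(z_bp = rnorm(n), z_ppt = rnorm(n), z_len = rnorm(n),
                      z_gc = rnorm(n), multi = rbinom(n, 1, 0.5))
  eta <- -f$z_bp - f$z_ppt - f$z_len + f$z_gc - f$multi
  delta_sep <- ifelse(eta > 0, 60, 0)  # perfectly separable at the threshold
  fit_sep <- suppressWarnings(
    fit_response(f, delta_sep, family = "binary", lambda_ridge = 1e-2))
  expect_true(all(is.finite(coef(fit_sep))))

  sim <- generate_event_set(sim_params(n_events = 1500L, seed = 71L))
  q <- quantify_events(sim$events, "DMSO", "SudC1")
  feats <- truth_features(sim$truth)
  planted <- sim$params$beta[-1]
  for (fam in c("fractional", "binary")) {
    fit <- fit_response(feats, q$delta, family = fam)
    expect_true(fit$converged)
    expect_equal(sign(coef(fit)[-1]), sign(planted), label = fam)
  }
  # the fractional fit recovers magnitude far better than the binary one
  err <- function(fit) max(abs(coef(fit)[-1] - planted) / abs(planted))
  expect_lt(err(fit_response(feats, q$delta, family = "fractional")),
            err(fit_response(feats, q$delta, family = "binary")))
})

test_that("tidy and glance expose the fit in broom style", {
  sim <- generate_event_set(small_params(n_events = 200L))
  q <- quantify_events(sim$events, "DMSO", "SudC1")
  fit <- fit_response(truth_features(sim$truth), q$delta)
  td <- generics::tidy(fit)
  expect_equal(td$term, c("b0", "bp", "ppt", "len", "gc", "multi"))
  expect_equal(td$estimate, unname(coef(fit)))
  gl <- generics::glance(fit)
  expect_equal(gl$n, sum(!is.na(q$delta)))
  expect_true(gl$converged)
})
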