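#' Parameters of the synthetic splicing cohort generator
#'
#' The generator emulates the statistical structure the transcriptome
#' analysis assumes: intron 3' ends whose drug response depends, through a
#' logistic model, on branch-point strength, polypyrimidine-tract
#' strength, intron length, GC content, and the presence of additional
#' branch-point consensus matches 5' of the main BP (which protect).
#'
#' Defaults define the study conditions: a cohort of 2,000 retained-intron
#' events (the most abundant drug-affected class), log-normal intron
#' lengths (mu 3.2, sigma 0.55 in log10 nt, truncated to 70-100,000 nt),
#' Beta(14, 16) GC content, a BP heptamer pool spanning U2 pairing scores
#' 3-6, extra-BP probability 0.5, planted coefficients
#' beta = (0, 1, 1, 1, 1, 1) for (intercept, BP, PPT, length, GC,
#' multi-BP), maximal drug response 60 percent points, event-level noise
#' s.d. 3 points, and negative-binomial junction coverage with mean 50.
#'
#' @param n_events number of events.
#' @param ir_fraction fraction of events that are retained introns (the
#'   rest are cassette exons).
#' @param len_log10_mu,len_log10_sd intron length distribution in log10 nt.
#' @param len_range allowed intron length range (nt); lengths outside are
#'   resampled.
#' @param gc_shape1,gc_shape2 Beta parameters of intron GC content.
#' @param bp_pool heptamers (branch A at position 6) planted as main BPs.
#' @param bp_offset_range heptamer start offsets (negative, -1 = last
#'   intron nt) for the main BP.
#' @param extra_bp_prob probability of planting 1-2 additional YNYYRAY
#'   matches in positions -100..-41.
#' @param beta named numeric: `b0`, `bp`, `ppt`, `len`, `gc`, `multi` —
#'   logistic coefficients of the response model.
#' @param delta_max maximal drug-induced change (percent points).
#' @param noise_sd event-level Gaussian noise on the treated PSI/PIR.
#' @param coverage_mean,coverage_size negative-binomial junction coverage.
#' @param n_replicates replicates per condition.
#' @param control,treated condition names used for sample columns.
#' @param seed integer seed; mandatory, the run is fully reproducible.
#' @return a `bs_sim_params` list.
#' @export
sim_params <- function(n_events = 2000L,
                       ir_fraction = 1,
                       len_log10_mu = 3.2, len_log10_sd = 0.55,
                       len_range = c(70L, 100000L),
                       gc_shape1 = 14, gc_shape2 = 16,
                       bp_pool = c("TACTAAC", "TGCTAAC", "TACTAAT",
                                   "CACTAAC", "TTCTAAC", "CTCTAAC",
                                   "CTCCAAC", "CTCTCAC"),
                       bp_offset_range = c(-40L, -18L),
                       extra_bp_prob = 0.5,
                       beta = c(b0 = 0, bp = 1, ppt = 1, len = 1,
                                gc = 1, multi = 1),
                       delta_max = 60,
                       noise_sd = 3,
                       coverage_mean = 50, coverage_size = 10,
                       n_replicates = 2L,
                       control = "DMSO", treated = "SudC1",
                       seed = 1L) {
  stopifnot(n_events >= 1, ir_fraction >= 0, ir_fraction <= 1,
            length(beta) == 6L, delta_max >= 0, noise_sd >= 0,
            coverage_mean > 0, n_replicates >= 1,
            is.numeric(seed), length(seed) == 1L, !is.na(seed))
  names(beta) <- c("b0", "bp", "ppt", "len", "gc", "multi")
  stopifnot(all(nchar(bp_pool) == 7L),
            all(substr(bp_pool, 6, 6) == "A"))
  structure(as.list(environment()), class = "bs_sim_params")
}

#' @export
print.bs_sim_params <- function(x, ...) {
  cat(sprintf("<bs_sim_params> %d events (%.0f%% IR), delta_max %g, seed %d\n",
              x$n_events, 100 * x$ir_fraction, x$delta_max, as.integer(x$seed)))
  cat("beta:", paste(sprintf("%s=%g", names(x$beta), x$beta), collapse = ", "), "\n")
  invisible(x)
}

# random background base sampler at target GC
random_seq <- function(len, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste0(sample(DNA_BASES, len, replace = TRUE, prob = p[DNA_BASES]),
         collapse = "")
}

# draw a YNYYRAY-conforming heptamer
random_ynyyray <- function() {
  paste0(vapply(seq_chars("YNYYRAY"), function(code) {
    sample(IUPAC_SETS[[code]], 1L)
  }, character(1)), collapse = "")
}

# replace positions [at, at+nchar(piece)-1] (1-based) of s with piece
splice_in <- function(s, at, piece) {
  paste0(substr(s, 1L, at - 1L), piece, substr(s, at + nchar(piece), nchar(s)))
}

# planted polypyrimidine tract; strength in [0,1] controls length and
# T-richness so measured ppt_score increases monotonically with strength
ppt_tract <- function(strength) {
  len <- 8L + round(16 * strength)
  p_y <- 0.55 + 0.4 * strength
  p_t <- 0.5 + 0.45 * strength
  bases <- ifelse(runif(len) < p_y,
                  ifelse(runif(len) < p_t, "T", "C"),
                  sample(c("A", "G"), len, replace = TRUE))
  paste0(bases, collapse = "")
}

# one synthetic intron + its planting record (assumes RNG state is set)
generate_one_intron <- function(params, name) {
  repeat {
    len <- round(10^rnorm(1, params$len_log10_mu, params$len_log10_sd))
    if (len >= params$len_range[1] && len <= params$len_range[2]) break
  }
  gc <- rbeta(1, params$gc_shape1, params$gc_shape2)
  s <- random_seq(len, gc)
  bp_offset <- sample(seq(params$bp_offset_range[1],
                          params$bp_offset_range[2]), 1L)
  heptamer <- sample(params$bp_pool, 1L)
  s <- splice_in(s, len + bp_offset + 1L, heptamer)
  branch_offset <- bp_offset + 5L
  ppt_strength <- runif(1)
  tract <- ppt_tract(ppt_strength)
  # tract sits directly 5' of position -3; clip so it never overwrites the BP
  max_len <- (-3L) - (bp_offset + 7L) + 1L
  if (nchar(tract) > max_len) tract <- substr(tract, 1L, max_len)
  if (nchar(tract) > 0L) {
    s <- splice_in(s, len + (-2L - nchar(tract)) + 1L, tract)
  }
  n_extra <- 0L
  if (runif(1) < params$extra_bp_prob) {
    n_want <- sample(1:2, 1L)
    lo <- max(-min(100L, len), -100L)
    starts <- seq(lo, -41L - 6L)
    if (length(starts) >= 7L) {
      placed <- integer(0)
      for (k in seq_len(n_want)) {
        free <- starts[vapply(starts, function(o) {
          all(abs(o - placed) >= 7L)
        }, logical(1))]
        if (length(free) == 0L) break
        o <- if (length(free) == 1L) free else sample(free, 1L)
        s <- splice_in(s, len + o + 1L, random_ynyyray())
        placed <- c(placed, o)
        n_extra <- n_extra + 1L
      }
    }
  }
  s <- splice_in(s, len - 1L, "AG")
  list(
    intron = tibble(name = name, chrom = name, start = 0L, end = len,
                    strand = "+", seq = s, len = len),
    truth = tibble(name = name, len = len, gc_target = gc,
                   bp_heptamer = heptamer, bp_offset = bp_offset,
                   branch_offset = branch_offset,
                   bp_pairing = u2_pairing_score(heptamer),
                   ppt_strength = ppt_strength,
                   n_extra_bp = n_extra, multi_bp = n_extra > 0L))
}

#' Generate synthetic introns with planted 3' splice site features
#'
#' Each intron is random background sequence at a Beta-drawn GC target
#' with: a branch-point heptamer from the pool planted at a drawn offset;
#' a polypyrimidine tract of drawn strength planted between the BP and
#' position -3; the terminal dinucleotide forced to AG; and, with
#' probability `extra_bp_prob`, 1-2 additional YNYYRAY matches planted in
#' positions -100..-41.
#'
#' @param params a [sim_params()] object.
#' @param names optional intron names.
#' @return list with `introns` (tibble compatible with [score_introns()])
#'   and `truth` (the planting record per intron).
#' @export
generate_introns <- function(params, names = NULL) {
  stopifnot(inherits(params, "bs_sim_params"))
  names <- names %||% sprintf("sim_intron_%05d", seq_len(params$n_events))
  withr::with_seed(as.integer(params$seed), {
    out <- purrr::map(names, function(nm) generate_one_intron(params, nm))
  })
  list(introns = purrr::map_dfr(out, "intron"),
       truth = purrr::map_dfr(out, "truth"))
}

#' Planted drug response of one event under the logistic model
#'
#' `delta = delta_max * logistic(b0 - b_bp z_bp - b_ppt z_ppt -
#' b_len z_len + b_gc z_gc - b_multi multi)`: weak BPs and PPTs, short and
#' GC-rich introns respond; additional BP matches protect. The sign is
#' positive for retained introns (retention goes up) and negative for
#' cassette exons (inclusion goes down).
#'
#' @param features tibble with standardized columns `z_bp`, `z_ppt`,
#'   `z_len`, `z_gc` and indicator `multi` (z-scores over the cohort).
#' @param beta named coefficients `b0`, `bp`, `ppt`, `len`, `gc`, `multi`.
#' @param delta_max maximal response in percent points.
#' @param type `"IR"` or `"CE"` per event (sets the sign).
#' @return numeric vector of true delta values.
#' @export
true_response <- function(features, beta, delta_max, type = "IR") {
  stopifnot(all(c("z_bp", "z_ppt", "z_len", "z_gc", "multi") %in%
                  names(features)))
  eta <- beta[["b0"]] -
    beta[["bp"]] * features$z_bp -
    beta[["ppt"]] * features$z_ppt -
    beta[["len"]] * features$z_len +
    beta[["gc"]] * features$z_gc -
    beta[["multi"]] * as.numeric(features$multi)
  magnitude <- delta_max * plogis(eta)
  sign <- if_else(rep_len(type, nrow(features)) == "IR", 1, -1)
  sign * magnitude
}

# z-score helper tolerant of zero variance
zscore <- function(x) {
  s <- sd(x)
  if (is.na(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Standardized planted features of a simulated cohort
#'
#' @param truth planting-record tibble from [generate_introns()] or a
#'   [generate_event_set()] result.
#' @return tibble with `z_bp`, `z_ppt`, `z_len`, `z_gc`, `multi`.
#' @export
truth_features <- function(truth) {
  if (is.list(truth) && !is.data.frame(truth) && !is.null(truth$truth)) {
    truth <- truth$truth
  }
  tibble(
    z_bp = zscore(truth$bp_pairing),
    z_ppt = zscore(truth$ppt_strength),
    z_len = zscore(log10(truth$len)),
    z_gc = zscore(truth$gc_target),
    multi = as.numeric(truth$multi_bp))
}

#' Generate a full synthetic event set with junction counts
#'
#' Combines [generate_introns()] with the logistic response model: control
#' PSI/PIR is Beta-distributed (high inclusion for cassette exons, low
#' retention for introns), the treated value is control plus the planted
#' response plus N(0, `noise_sd`) truncated to \[0, 100\], junction read
#' counts are Binomial draws at negative-binomial per-sample coverage, and
#' host-gene FPKM is log-normal and independent of the response (a built-in
#' null for the expression-splicing correlation).
#'
#' @param params a [sim_params()] object.
#' @return list of class `bs_sim`: `events` (wide event table, see
#'   [read_event_table()]), `introns`, `truth` (planting record plus
#'   `delta_true`, `psi_control_true`, `psi_treated_true`, `fpkm`),
#'   `params`.
#' @export
generate_event_set <- function(params = sim_params()) {
  stopifnot(inherits(params, "bs_sim_params"))
  gen <- generate_introns(params)
  truth <- gen$truth
  n <- nrow(truth)
  withr::with_seed(as.integer(params$seed) + 1L, {
    type <- if_else(runif(n) < params$ir_fraction, "IR", "CE")
    feats <- truth_features(truth)
    delta_true <- true_response(feats, params$beta, params$delta_max, type)
    psi0 <- if_else(type == "IR",
                    100 * rbeta(n, 1.5, 15),
                    100 * rbeta(n, 15, 1.5))
    psi1 <- pmin(100, pmax(0, psi0 + delta_true + rnorm(n, 0, params$noise_sd)))
    fpkm <- rlnorm(n, meanlog = 2, sdlog = 1.2)
    samples <- c(paste0(params$control, "_", seq_len(params$n_replicates)),
                 paste0(params$treated, "_", seq_len(params$n_replicates)))
    is_treated <- rep(c(FALSE, TRUE), each = params$n_replicates)
    events <- tibble(
      EVENT_ID = truth$name, GENE_ID = paste0("gene_", truth$name),
      TYPE = type, CHROM = truth$name, STRAND = "+",
      COORDS = paste0("0-", truth$len))
    for (i in seq_along(samples)) {
      s <- samples[i]
      p <- (if (is_treated[i]) psi1 else psi0) / 100
      cov <- function() pmax(1L, rnbinom(n, mu = params$coverage_mean,
                                         size = params$coverage_size))
      a <- rbinom(n, cov(), p)
      b <- rbinom(n, cov(), p)
      e <- rbinom(n, cov(), 1 - p)
      events[[paste0("INC1_", s)]] <- if_else(type == "CE", a, NA_integer_)
      events[[paste0("INC2_", s)]] <- if_else(type == "CE", b, NA_integer_)
      events[[paste0("EXC_", s)]] <- if_else(type == "CE", e, NA_integer_)
      events[[paste0("EI1_", s)]] <- if_else(type == "IR", a, NA_integer_)
      events[[paste0("EI2_", s)]] <- if_else(type == "IR", b, NA_integer_)
      events[[paste0("EE_", s)]] <- if_else(type == "IR", e, NA_integer_)
      events[[paste0("FPKM_", s)]] <- fpkm * rlnorm(n, 0, 0.05)
    }
  })
  truth <- truth |>
    mutate(type = type, delta_true = delta_true,
           psi_control_true = psi0, psi_treated_true = psi1, fpkm = fpkm)
  structure(list(events = events, introns = gen$introns, truth = truth,
                 params = params),
            class = "bs_sim")
}

#' @export
print.bs_sim <- function(x, ...) {
  cat(sprintf("<bs_sim> %d events (%d IR / %d CE), seed %d\n",
              nrow(x$truth), sum(x$truth$type == "IR"),
              sum(x$truth$type == "CE"), as.integer(x$params$seed)))
  invisible(x)
}

#' Recover response-model coefficients from observed splicing changes
#'
#' Fits the generator's logistic response model back from a simulated
#' cohort by L2-regularised iteratively reweighted least squares
#' (intercept unpenalised). Two estimators are available:
#'
#' * `family = "fractional"` (default): fractional-logit fit of
#'   `|delta| / delta_max` — the generative mean model itself. This
#'   recovers both the signs and the magnitudes of the planted
#'   coefficients.
#' * `family = "binary"`: binarises the response at
#'   `|delta| >= threshold` and fits ridge logistic regression.
#'   Thresholding a noisy deterministic response identifies the
#'   coefficient vector's direction but not its scale (the fitted slopes
#'   absorb the inverse noise scale), so this variant is reliable for
#'   sign recovery only.
#'
#' Fitted slopes are mapped back to the generator's parameterisation
#' (`bp`, `ppt`, `len`, `multi` enter the planted model with a minus
#' sign, `gc` with a plus), so `coef(fit)` is directly comparable to the
#' planted `beta`.
#'
#' @param features tibble with columns `z_bp`, `z_ppt`, `z_len`, `z_gc`,
#'   `multi` (see [truth_features()]).
#' @param delta observed delta-PSI/PIR per event.
#' @param family `"fractional"` or `"binary"` (see Details).
#' @param delta_max maximal response used to scale the fractional fit.
#' @param lambda_ridge L2 penalty on the slope coefficients.
#' @param threshold regulation threshold (percent points; binary family).
#' @param max_iter,tol IRLS stopping rule (`max |step| < tol`).
#' @return object of class `bs_response_fit` with elements
#'   `coefficients` (generator parameterisation: `b0`, `bp`, `ppt`,
#'   `len`, `gc`, `multi`), `raw_coefficients` (design scale), `family`,
#'   `converged`, `iterations`, `lambda`, `n`, `n_regulated`.
#' @export
fit_response <- function(features, delta,
                         family = c("fractional", "binary"),
                         delta_max = 60, lambda_ridge = 1e-4,
                         threshold = 25, max_iter = 100L, tol = 1e-8) {
  stopifnot(all(c("z_bp", "z_ppt", "z_len", "z_gc", "multi") %in%
                  names(features)))
  family <- arg_match(family)
  keep <- !is.na(delta)
  X <- cbind(1, as.matrix(features[keep, c("z_bp", "z_ppt", "z_len",
                                           "z_gc", "multi")]))
  colnames(X)[1] <- "(Intercept)"
  y <- if (family == "binary") {
    as.numeric(abs(delta[keep]) >= threshold)
  } else {
    pmin(1, pmax(0, abs(delta[keep]) / delta_max))
  }
  p_dim <- ncol(X)
  if (nrow(X) < 10 * p_dim) {
    abort(sprintf("fit_response() requires n >= %d events", 10 * p_dim))
  }
  R <- diag(c(0, rep(lambda_ridge, p_dim - 1L)))
  b <- numeric(p_dim)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(X %*% b)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    b_new <- drop(solve(crossprod(X, w * X) + R, crossprod(X, w * z)))
    step <- max(abs(b_new - b))
    b <- b_new
    if (step < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf("fit_response() did not converge in %d iterations", max_iter))
  }
  # map design-scale slopes back to the generator's sign convention
  sign_map <- c(1, -1, -1, -1, 1, -1)
  coef_gen <- setNames(b * sign_map,
                       c("b0", "bp", "ppt", "len", "gc", "multi"))
  structure(
    list(coefficients = coef_gen,
         raw_coefficients = setNames(b, colnames(X)),
         family = family, converged = converged, iterations = iter,
         lambda = lambda_ridge, threshold = threshold, n = nrow(X),
         n_regulated = sum(abs(delta[keep]) >= threshold)),
    class = "bs_response_fit")
}

#' @export
print.bs_response_fit <- function(x, ...) {
  cat(sprintf("<bs_response_fit> n = %d (%d regulated), %s in %d iterations\n",
              x$n, x$n_regulated,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  print(round(x$coefficients, 3))
  invisible(x)
}

#' @export
coef.bs_response_fit <- function(object, ...) object$coefficients

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_response
#' @param x a `bs_response_fit` object.
#' @param ... unused.
#' @export
tidy.bs_response_fit <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients),
         raw = unname(x$raw_coefficients))
}

#' @rdname fit_response
#' @export
glance.bs_response_fit <- function(x, ...) {
  tibble(n = x$n, n_regulated = x$n_regulated, family = x$family,
         lambda = x$lambda, threshold = x$threshold,
         iterations = x$iterations, converged = x$converged)
}
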