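#' Build a position weight matrix object
#'
#' Rows are positions, columns the bases A, C, G, T. Input rows may be
#' counts or probabilities; each row is normalised after adding
#' `pseudocount` to every cell. Scores are log2 odds against `background`.
#'
#' @param mat numeric matrix (positions x 4) of counts or probabilities.
#' @param pseudocount value added to each cell before normalisation.
#' @param background length-4 probability vector over A, C, G, T.
#' @return an object of class `bs_pwm`: list with `width`, `probs`
#'   (positions x 4, rows summing to 1), `pseudocount`, `background`.
#' @export
pwm <- function(mat, pseudocount = 0.01, background = rep(0.25, 4)) {
  mat <- as.matrix(mat)
  if (ncol(mat) != 4L) abort("PWM matrix must have 4 columns (A, C, G, T)")
  if (nrow(mat) < 1L) abort("PWM must have width >= 1")
  if (any(mat < 0) || any(!is.finite(mat))) abort("PWM cells must be finite and non-negative")
  rs <- rowSums(mat)
  if (any(rs <= 0)) {
    abort(sprintf("PWM row %d does not sum to a positive value", which(rs <= 0)[1]))
  }
  stopifnot(length(background) == 4L, all(background > 0))
  background <- background / sum(background)
  probs <- (mat + pseudocount) / (rs + 4 * pseudocount)
  dimnames(probs) <- list(NULL, DNA_BASES)
  structure(
    list(width = nrow(probs), probs = probs,
         pseudocount = pseudocount, background = setNames(background, DNA_BASES)),
    class = "bs_pwm")
}

#' @export
print.bs_pwm <- function(x, ...) {
  cat(sprintf("<bs_pwm> width %d, pseudocount %g\n", x$width, x$pseudocount))
  print(round(x$probs, 3))
  invisible(x)
}

#' Read a PWM from a 4-column TSV file
#'
#' One row per position, tab-separated columns A, C, G, T (counts or
#' probabilities, with or without a header line naming the bases).
#'
#' @inheritParams pwm
#' @param path path to the TSV file.
#' @return a `bs_pwm` object.
#' @export
read_pwm <- function(path, pseudocount = 0.01, background = rep(0.25, 4)) {
  if (!file.exists(path)) abort(paste0("PWM file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort(paste0("PWM file is empty: ", path))
  if (grepl("^[ACGTacgt\\s\t ]+$", lines[1]) && !grepl("[0-9]", lines[1])) {
    lines <- lines[-1]
  }
  if (length(lines) == 0L) abort(paste0("PWM file has no data rows: ", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 4L)) {
    abort(sprintf("PWM row %d does not have 4 tab-separated fields",
                  which(lengths(fields) != 4L)[1]))
  }
  mat <- matrix(suppressWarnings(as.numeric(unlist(fields))),
                ncol = 4L, byrow = TRUE)
  if (anyNA(mat)) abort("PWM file contains non-numeric cells")
  pwm(mat, pseudocount = pseudocount, background = background)
}

#' Write a PWM's probability matrix as 4-column TSV
#'
#' @param x a `bs_pwm` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(x, path) {
  stopifnot(inherits(x, "bs_pwm"))
  readr::write_tsv(as_tibble(x$probs), path, progress = FALSE)
  invisible(path)
}

#' Default SF1 branch-point binding matrix
#'
#' A stand-in SF1 PWM constructed from the degenerate branch-point
#' consensus YNYYRAY: each position distributes weight equally over its
#' allowed bases (Y = C/T, R = A/G, N = any), then a pseudocount is
#' applied. Users with the published SF1 matrix can load it with
#' [read_pwm()] and pass it anywhere a PWM is accepted.
#'
#' @param pseudocount pseudocount applied during normalisation.
#' @return a `bs_pwm` of width 7.
#' @export
sf1_pwm <- function(pseudocount = 0.01) {
  rows <- lapply(seq_chars("YNYYRAY"), function(code) {
    allowed <- IUPAC_SETS[[code]]
    w <- setNames(numeric(4), DNA_BASES)
    w[allowed] <- 1 / length(allowed)
    w
  })
  pwm(do.call(rbind, rows), pseudocount = pseudocount)
}
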