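# mandatory identity columns of an event table
EVENT_META_COLS <- c("EVENT_ID", "GENE_ID", "TYPE", "CHROM", "STRAND", "COORDS")

#' Read a splicing event table
#'
#' Tab-separated layout: mandatory columns `EVENT_ID`, `GENE_ID`, `TYPE`
#' (`CE` or `IR`), `CHROM`, `STRAND`, `COORDS` (BED-style `start-end`),
#' then per sample `s` the junction read counts `INC1_s`, `INC2_s`,
#' `EXC_s` (cassette exons) or `EI1_s`, `EI2_s`, `EE_s` (retained
#' introns), plus `FPKM_s` for the host gene. Inclusion/exon-intron counts
#' may be NA on rows of the other event type.
#'
#' @param path path to the TSV file.
#' @return a tibble (one row per event) with an attribute `"samples"`
#'   giving the sample names; also retrievable with [event_samples()].
#' @export
read_event_table <- function(path) {
  if (!file.exists(path)) abort(paste0("event table not found: ", path))
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    EVENT_ID = "c", GENE_ID = "c", TYPE = "c", CHROM = "c", STRAND = "c",
    COORDS = "c", .default = "d"), progress = FALSE)
  validate_event_table(tbl)
}

#' @rdname read_event_table
#' @param events an event table tibble.
#' @export
validate_event_table <- function(events) {
  missing_cols <- setdiff(EVENT_META_COLS, names(events))
  if (length(missing_cols)) {
    abort(paste0("event table is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!all(events$TYPE %in% c("CE", "IR"))) {
    abort("event table TYPE must be 'CE' or 'IR'")
  }
  if (anyDuplicated(events$EVENT_ID)) {
    abort(sprintf("duplicate EVENT_ID: %s",
                  events$EVENT_ID[duplicated(events$EVENT_ID)][1]))
  }
  samples <- event_samples(events)
  if (length(samples) == 0L) abort("event table has no FPKM_<sample> columns")
  if (anyDuplicated(samples)) abort("sample names must be unique")
  for (s in samples) {
    need <- paste0(c("FPKM_"), s)
    ce_need <- paste0(c("INC1_", "INC2_", "EXC_"), s)
    ir_need <- paste0(c("EI1_", "EI2_", "EE_"), s)
    if (any(events$TYPE == "CE")) need <- c(need, ce_need)
    if (any(events$TYPE == "IR")) need <- c(need, ir_need)
    missing_cols <- setdiff(need, names(events))
    if (length(missing_cols)) {
      abort(paste0("event table is missing count column(s): ",
                   paste(missing_cols, collapse = ", ")))
    }
    if (any(events$TYPE == "CE")) {
      bad <- events$TYPE == "CE" &
        !complete.cases(events[, ce_need, drop = FALSE])
      if (any(bad)) {
        abort(sprintf("CE event '%s' is missing a %s count",
                      events$EVENT_ID[bad][1], paste(ce_need, collapse = "/")))
      }
    }
    if (any(events$TYPE == "IR")) {
      bad <- events$TYPE == "IR" &
        !complete.cases(events[, ir_need, drop = FALSE])
      if (any(bad)) {
        abort(sprintf("IR event '%s' is missing a %s count",
                      events$EVENT_ID[bad][1], paste(ir_need, collapse = "/")))
      }
    }
  }
  count_cols <- grep("^(INC1|INC2|EXC|EI1|EI2|EE)_", names(events), value = TRUE)
  cnt <- as.matrix(events[, count_cols, drop = FALSE])
  if (any(cnt < 0, na.rm = TRUE)) abort("junction counts must be non-negative")
  as_tibble(events)
}

#' Sample names of an event table
#'
#' @param events an event table tibble.
#' @return character vector of sample names (from the `FPKM_` columns).
#' @export
event_samples <- function(events) {
  sub("^FPKM_", "", grep("^FPKM_", names(events), value = TRUE))
}

#' Write an event table to TSV
#'
#' Inverse of [read_event_table()]: `read_event_table(write_event_table(x))`
#' reproduces `x`.
#'
#' @param events an event table tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(events, path) {
  validate_event_table(events)
  readr::write_tsv(events, path, progress = FALSE)
  invisible(path)
}

#' Percent spliced in for a cassette exon
#'
#' `100 * (inc1 + inc2) / (inc1 + inc2 + 2 * exc)`: the two inclusion
#' junctions are averaged against the single exclusion junction. All-zero
#' counts give NA (no information).
#'
#' @param inc1,inc2 upstream/downstream inclusion junction read counts.
#' @param exc exclusion (skipping) junction read counts.
#' @return numeric vector of PSI percentages in \[0, 100\] (or NA).
#' @export
psi_ce <- function(inc1, inc2, exc) {
  stopifnot(all(inc1 >= 0, na.rm = TRUE), all(inc2 >= 0, na.rm = TRUE),
            all(exc >= 0, na.rm = TRUE))
  inc <- inc1 + inc2
  total <- inc + 2 * exc
  ifelse(inc1 + inc2 + exc > 0, 100 * inc / total, NA_real_)
}

#' Percent intron retention
#'
#' `100 * mean(ei1, ei2) / (mean(ei1, ei2) + ee)`: the two exon-intron
#' junctions are averaged against the spliced exon-exon junction. All-zero
#' counts give NA.
#'
#' @param ei1,ei2 exon-intron junction read counts (5' and 3').
#' @param ee spliced exon-exon junction read counts.
#' @return numeric vector of PIR percentages in \[0, 100\] (or NA).
#' @export
pir <- function(ei1, ei2, ee) {
  stopifnot(all(ei1 >= 0, na.rm = TRUE), all(ei2 >= 0, na.rm = TRUE),
            all(ee >= 0, na.rm = TRUE))
  m <- (ei1 + ei2) / 2
  ifelse(ei1 + ei2 + ee > 0, 100 * m / (m + ee), NA_real_)
}

#' Treated-minus-control splicing change
#'
#' @param treated,control PSI or PIR percentages (replicate-averaged).
#' @return `treated - control`; NA propagates.
#' @export
delta_psi <- function(treated, control) treated - control

#' Classify events by splicing change
#'
#' Paper-convention thresholds: `|delta| >= dpsi_regulated` (default 25) is
#' regulated, with the sign giving direction; `|delta| <= dpsi_nondiff`
#' (default 5) is non-differential; values in between are intermediate.
#' Events with fewer than `min_reads` informative reads in either condition
#' are `low_coverage` regardless of delta. Boundaries are closed: delta of
#' exactly 25 is regulated, exactly 5 non-differential.
#'
#' @param delta numeric vector of delta-PSI/PIR percentages.
#' @param reads minimum of the per-condition informative read totals
#'   (recycled if length 1; `Inf` to disable the filter).
#' @param min_reads coverage threshold (reads per condition).
#' @param dpsi_regulated,dpsi_nondiff class thresholds in percent points.
#' @return factor with levels `regulated_up`, `regulated_down`,
#'   `intermediate`, `nondiff`, `low_coverage`.
#' @export
classify_delta <- function(delta, reads = Inf, min_reads = 10,
                           dpsi_regulated = 25, dpsi_nondiff = 5) {
  stopifnot(dpsi_nondiff < dpsi_regulated)
  reads <- rep_len(reads, length(delta))
  cls <- dplyr::case_when(
    is.na(delta) | reads < min_reads ~ "low_coverage",
    delta >= dpsi_regulated ~ "regulated_up",
    delta <= -dpsi_regulated ~ "regulated_down",
    abs(delta) <= dpsi_nondiff ~ "nondiff",
    TRUE ~ "intermediate")
  factor(cls, levels = c("regulated_up", "regulated_down", "intermediate",
                         "nondiff", "low_coverage"))
}

# samples belonging to a condition: exact name or "<condition>_<replicate>"
condition_samples <- function(samples, condition) {
  hit <- samples == condition | startsWith(samples, paste0(condition, "_"))
  if (!any(hit)) {
    abort(sprintf("no samples found for condition '%s' (samples: %s)",
                  condition, paste(samples, collapse = ", ")))
  }
  samples[hit]
}

# per-condition replicate-averaged PSI/PIR and informative read totals
condition_psi <- function(events, cond_samples) {
  n <- nrow(events)
  col <- function(prefix, s) {
    cn <- paste0(prefix, "_", s)
    if (cn %in% names(events)) events[[cn]] else rep(NA_real_, n)
  }
  psi_mat <- sapply(cond_samples, function(s) {
    ifelse(events$TYPE == "CE",
           psi_ce(col("INC1", s), col("INC2", s), col("EXC", s)),
           pir(col("EI1", s), col("EI2", s), col("EE", s)))
  })
  reads_mat <- sapply(cond_samples, function(s) {
    ifelse(events$TYPE == "CE",
           col("INC1", s) + col("INC2", s) + col("EXC", s),
           col("EI1", s) + col("EI2", s) + col("EE", s))
  })
  psi_mat <- matrix(psi_mat, nrow = n)
  reads_mat <- matrix(reads_mat, nrow = n)
  list(psi = rowMeans(psi_mat, na.rm = TRUE),
       reads = rowSums(reads_mat, na.rm = TRUE))
}

#' Quantify and classify splicing events between two conditions
#'
#' Computes PSI (cassette exons) or PIR (retained introns) per replicate,
#' averages replicates within each condition, takes the treated-minus-
#' control difference, and classifies each event with [classify_delta()].
#'
#' @param events an event table (see [read_event_table()]).
#' @param control,treated condition names; a sample belongs to a condition
#'   when its name is the condition or `condition_replicate`.
#' @inheritParams classify_delta
#' @return tibble with `event_id`, `gene_id`, `type`, `psi_control`,
#'   `psi_treated`, `delta`, `reads_control`, `reads_treated`, `covered`,
#'   `class`, `fpkm` (control-sample mean).
#' @export
quantify_events <- function(events, control, treated, min_reads = 10,
                            dpsi_regulated = 25, dpsi_nondiff = 5) {
  events <- validate_event_table(events)
  samples <- event_samples(events)
  ctrl <- condition_psi(events, condition_samples(samples, control))
  trt <- condition_psi(events, condition_samples(samples, treated))
  fpkm_cols <- paste0("FPKM_", condition_samples(samples, control))
  fpkm <- rowMeans(as.matrix(events[, fpkm_cols, drop = FALSE]), na.rm = TRUE)
  delta <- delta_psi(trt$psi, ctrl$psi)
  reads_min <- pmin(ctrl$reads, trt$reads)
  tibble(
    event_id = events$EVENT_ID, gene_id = events$GENE_ID, type = events$TYPE,
    psi_control = ctrl$psi, psi_treated = trt$psi, delta = delta,
    reads_control = ctrl$reads, reads_treated = trt$reads,
    covered = reads_min >= min_reads,
    class = classify_delta(delta, reads = reads_min, min_reads = min_reads,
                           dpsi_regulated = dpsi_regulated,
                           dpsi_nondiff = dpsi_nondiff),
    fpkm = fpkm)
}

#' Regulated event id sets per drug and direction
#'
#' @param quantified named list of tibbles from [quantify_events()], one
#'   per drug, over the same event universe.
#' @param dpsi_regulated threshold on `|delta|` defining regulation.
#' @return tibble with columns `drug`, `direction` (`up`/`down`) and
#'   `event_id`, sorted for reproducibility. Convert to plain sets with
#'   `split(x$event_id, paste(x$drug, x$direction))`.
#' @export
regulated_sets <- function(quantified, dpsi_regulated = 25) {
  stopifnot(is.list(quantified), length(quantified) >= 1,
            !is.null(names(quantified)))
  universe <- sort(quantified[[1]]$event_id)
  for (d in names(quantified)) {
    u <- sort(quantified[[d]]$event_id)
    if (!identical(u, universe)) {
      diff_ids <- c(setdiff(u, universe), setdiff(universe, u))
      abort(paste0("event universes differ ('", d, "'): ",
                   paste(head(diff_ids, 5), collapse = ", ")))
    }
  }
  purrr::imap_dfr(quantified, function(q, drug) {
    reg <- q[!is.na(q$delta) & abs(q$delta) >= dpsi_regulated &
               q$class != "low_coverage", ]
    tibble(drug = drug,
           direction = if_else(reg$delta > 0, "up", "down"),
           event_id = reg$event_id)
  }) |>
    arrange(.data$drug, .data$direction, .data$event_id)
}
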