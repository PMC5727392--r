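pipeline_log <- function(quiet, stage, fmt, ...) {
  if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Default pipeline configuration
#'
#' @return a list with the configuration keys understood by
#'   [run_pipeline()]: `sim` (overrides for [sim_params()]), `bp_window`,
#'   `multi_bp_window`, `min_reads`, `dpsi_regulated`, `dpsi_nondiff`,
#'   `rna_map` (`pattern`, `width`, `smooth`).
#' @export
default_config <- function() {
  list(
    sim = list(),
    bp_window = 150L, multi_bp_window = 100L,
    min_reads = 10, dpsi_regulated = 25, dpsi_nondiff = 5,
    rna_map = list(pattern = "YNYYRAY", width = 150L, smooth = 15L))
}

read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  cfg <- modifyList(default_config(), config)
  known <- names(formals(sim_params))
  bad <- setdiff(names(cfg$sim), known)
  if (length(bad)) {
    abort(paste0("unknown sim config field(s): ", paste(bad, collapse = ", ")))
  }
  cfg
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates simulate -> features -> quantify/classify -> compare ->
#' RNA map -> overlaps as one reproducible run. Every stage writes a TSV
#' (or FASTA/BED) under `out_dir`; the run manifest records the config,
#' seed, per-stage outputs and their MD5 checksums. The pipeline is a pure
#' function of the config: identical configs give byte-identical outputs
#' (timestamps live only in the manifest).
#'
#' @param config a config list or path to a JSON config file (see
#'   [default_config()]); `config$sim` overrides [sim_params()] defaults.
#' @param out_dir output directory (created if needed).
#' @param seed optional seed overriding `config$sim$seed`.
#' @param quiet suppress progress messages (written to stderr).
#' @return the manifest (class `bs_manifest`), invisibly; also written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config = default_config(), out_dir, seed = NULL,
                         quiet = FALSE) {
  cfg <- read_config(config)
  if (!is.null(seed)) cfg$sim$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  out <- function(name) file.path(out_dir, name)

  params <- do.call(sim_params, cfg$sim)
  pipeline_log(quiet, "simulate", "generating %d events (seed %d)",
               params$n_events, as.integer(params$seed))
  sim <- generate_event_set(params)
  write_fasta(setNames(sim$introns$seq, sim$introns$name),
              paths$fasta <- out("sequences.fa"))
  write_bed_introns(sim$introns, paths$bed <- out("introns.bed"))
  write_event_table(sim$events, paths$events <- out("events.tsv"))
  readr::write_tsv(sim$truth, paths$truth <- out("truth.tsv"), progress = FALSE)

  pipeline_log(quiet, "features", "scoring %d introns (bp window %d nt)",
               nrow(sim$introns), cfg$bp_window)
  features <- score_introns(sim$introns, bp_window = cfg$bp_window,
                            multi_bp_window = cfg$multi_bp_window)
  readr::write_tsv(features, paths$features <- out("features.tsv"),
                   progress = FALSE)

  pipeline_log(quiet, "quantify", "PSI/PIR %s vs %s (min reads %g)",
               params$treated, params$control, cfg$min_reads)
  quant <- quantify_events(sim$events, control = params$control,
                           treated = params$treated,
                           min_reads = cfg$min_reads,
                           dpsi_regulated = cfg$dpsi_regulated,
                           dpsi_nondiff = cfg$dpsi_nondiff)
  readr::write_tsv(quant, paths$quantified <- out("quantified.tsv"),
                   progress = FALSE)
  class_counts <- quant |> dplyr::count(.data$class, name = "n_events")
  pipeline_log(quiet, "quantify", "classes: %s",
               paste(sprintf("%s=%d", class_counts$class,
                             class_counts$n_events), collapse = ", "))

  joined <- features |>
    rename(event_id = "name") |>
    left_join(quant, by = "event_id") |>
    mutate(seq = sim$introns$seq[match(.data$event_id, sim$introns$name)]) |>
    mutate(group = dplyr::case_when(
      .data$class %in% c("regulated_up", "regulated_down") ~ "regulated",
      .data$class == "nondiff" ~ "nondiff",
      TRUE ~ NA_character_))
  cmp_features <- c("bp_best_pairing", "bp_best_pwm", "ppt_score",
                    "gc_intron", "len_intron")
  pipeline_log(quiet, "compare", "regulated (n=%d) vs nondiff (n=%d)",
               sum(joined$group == "regulated", na.rm = TRUE),
               sum(joined$group == "nondiff", na.rm = TRUE))
  comparisons <- compare_features(joined[!is.na(joined$group), ],
                                  "group", "regulated", "nondiff",
                                  features = cmp_features)
  readr::write_tsv(comparisons, paths$comparisons <- out("comparisons.tsv"),
                   progress = FALSE)

  multi <- joined |>
    filter(!is.na(.data$delta)) |>
    mutate(bp_group = if_else(.data$n_bp_matches_100 >= 2, "BPs", "1 BP"))
  multibp <- if (all(c("1 BP", "BPs") %in% multi$bp_group)) {
    mann_whitney_u(abs(multi$delta[multi$bp_group == "BPs"]),
                   abs(multi$delta[multi$bp_group == "1 BP"]),
                   feature = "abs_delta_multi_vs_single_bp")
  } else {
    tibble(feature = "abs_delta_multi_vs_single_bp", n1 = NA_integer_,
           n2 = NA_integer_, median1 = NA_real_, median2 = NA_real_,
           U = NA_real_, p_two_sided = NA_real_, direction = NA_real_,
           stars = NA_character_)
  }
  readr::write_tsv(multibp, paths$multibp <- out("multibp.tsv"),
                   progress = FALSE)

  grp <- joined[!is.na(joined$group), ]
  map_groups <- split(grp$seq, grp$group)
  if (length(map_groups) >= 1 && all(lengths(map_groups) > 0)) {
    pipeline_log(quiet, "rnamap", "%s profile over %d nt",
                 cfg$rna_map$pattern, cfg$rna_map$width)
    profile <- rna_map(map_groups, pattern = cfg$rna_map$pattern,
                       width = cfg$rna_map$width, smooth = cfg$rna_map$smooth)
    readr::write_tsv(as_tibble(profile), paths$rnamap <- out("rnamap.tsv"),
                     progress = FALSE)
  }

  sets_tbl <- regulated_sets(setNames(list(quant), params$treated),
                             dpsi_regulated = cfg$dpsi_regulated)
  readr::write_tsv(sets_tbl, paths$regulated <- out("regulated_sets.tsv"),
                   progress = FALSE)
  sets <- split(sets_tbl$event_id,
                paste(sets_tbl$drug, sets_tbl$direction, sep = "_"))
  if (length(sets) >= 2) {
    ov <- overlap_matrix(sets)
    readr::write_tsv(ov$regions, paths$overlap <- out("overlap.tsv"),
                     progress = FALSE)
  }

  manifest <- structure(list(
    tool = "branchsense",
    version = as.character(utils::packageVersion("branchsense")),
    created = format(Sys.time(), tz = "UTC"),
    seed = as.integer(params$seed),
    config = cfg,
    n_events = nrow(quant),
    class_counts = setNames(as.list(class_counts$n_events),
                            as.character(class_counts$class)),
    outputs = lapply(paths, normalizePath),
    checksums = as.list(tools::md5sum(unlist(lapply(paths, normalizePath))))
  ), class = "bs_manifest")
  jsonlite::write_json(unclass(manifest), file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  pipeline_log(quiet, "done", "%d outputs in %s", length(paths), out_dir)
  invisible(manifest)
}

#' Summarise a completed pipeline run
#'
#' @param run a `bs_manifest` from [run_pipeline()], or the path to a run
#'   directory containing `manifest.json`.
#' @return list with `comparisons` (star-annotated feature comparisons),
#'   `multibp`, `class_counts`, `summary` (character lines, also printed).
#' @export
report_run <- function(run) {
  if (is.character(run)) {
    mpath <- if (dir.exists(run)) file.path(run, "manifest.json") else run
    if (!file.exists(mpath)) abort(paste0("manifest not found: ", mpath))
    run <- structure(jsonlite::read_json(mpath, simplifyVector = TRUE),
                     class = "bs_manifest")
  }
  stopifnot(inherits(run, "bs_manifest"))
  needed <- c("comparisons", "multibp", "quantified")
  missing_stage <- setdiff(needed, names(run$outputs))
  if (length(missing_stage)) {
    abort(paste0("manifest is missing stage output(s): ",
                 paste(missing_stage, collapse = ", ")))
  }
  comparisons <- readr::read_tsv(run$outputs$comparisons,
                                 show_col_types = FALSE, progress = FALSE)
  multibp <- readr::read_tsv(run$outputs$multibp, show_col_types = FALSE,
                             progress = FALSE)
  lines <- c(
    sprintf("branchsense %s run (seed %d): %d events",
            run$version, run$seed, run$n_events),
    sprintf("  classes: %s",
            paste(sprintf("%s=%s", names(run$class_counts),
                          unlist(run$class_counts)), collapse = ", ")),
    "  feature comparisons (regulated vs nondiff, Mann-Whitney two-sided):")
  if (nrow(comparisons) > 0 && !all(is.na(comparisons$p_two_sided))) {
    lines <- c(lines, sprintf(
      "    %-16s median %8.3g vs %8.3g  p = %.3g %s",
      comparisons$feature, comparisons$median1, comparisons$median2,
      comparisons$p_two_sided, comparisons$stars))
  } else {
    lines <- c(lines, "    n = 0 in a group; no test run")
  }
  if (!all(is.na(multibp$p_two_sided))) {
    lines <- c(lines, sprintf(
      "  |delta| multi-BP vs single-BP: median %.3g vs %.3g, p = %.3g %s",
      multibp$median1, multibp$median2, multibp$p_two_sided, multibp$stars))
  }
  cat(lines, sep = "\n")
  invisible(list(comparisons = comparisons, multibp = multibp,
                 class_counts = run$class_counts, summary = lines))
}

#' @export
print.bs_manifest <- function(x, ...) {
  cat(sprintf("<bs_manifest> %s %s, seed %d, %d events, %d outputs\n",
              x$tool, x$version, x$seed, x$n_events, length(x$outputs)))
  invisible(x)
}
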