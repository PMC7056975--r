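# End-to-end orchestration: simulate -> scan -> filter -> screen -> classify,
# with every intermediate written as a plain-text table and a deterministic
# report (same config + seed => byte-identical outputs).

#' Run the full synthetic analysis chain
#'
#' Stages, in order: (1) simulate replicate-line allele frequencies and a
#' synthetic annotation table; (2) scan for divergence intervals and attach
#' genes; (3) select candidate genes; (4) simulate the RNAi screen and call
#' effects; (5) classify genes into pleiotropy categories. Writes
#' `variants.tsv`, `annotations.tsv`, `intervals.tsv`, `intervals.bed`,
#' `candidates.tsv`, `lifespan.csv`, `productivity.csv`, `qpcr.csv`,
#' `effect_calls.csv`, `profiles.csv`, `report.json` and `report.txt` under
#' `out_dir`. Any stage failure aborts with the stage name and cause.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param scan a [scan_params()].
#' @param filter a [filter_params()].
#' @param alpha per-test significance level for the effect calls.
#' @param early_weeks,late_weeks week sets for the early/late axis (see
#'   [classify_pleiotropy()]).
#' @param flank_bp gene-to-interval assignment flank (bp).
#' @return the report, invisibly: a list with per-arm interval summaries,
#'   candidate counts, screen tallies and category tallies.
#' @export
run_pipeline <- function(config, out_dir,
                         scan = scan_params(), filter = filter_params(),
                         alpha = 0.05, early_weeks = c(1L, 2L),
                         late_weeks = NULL, flank_bp = 0) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  variants <- stage("simulate", simulate_frequencies(config))
  annotations <- stage("simulate", simulate_annotations(config, variants))
  write_variants(variants, file.path(out_dir, "variants.tsv"))
  write_annotations(annotations, file.path(out_dir, "annotations.tsv"))

  intervals <- stage("scan", {
    iv <- scan_intervals(variants, scan)
    assign_genes(iv, annotations, flank_bp = flank_bp,
                 known_arms = config$arms$arm)
  })
  utils::write.table(intervals, file.path(out_dir, "intervals.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_intervals_bed(intervals, file.path(out_dir, "intervals.bed"))

  candidates <- stage("filter", select_candidates(annotations, intervals, filter))
  utils::write.table(candidates, file.path(out_dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  screen <- stage("screen", simulate_screen(config))
  write_phenotypes(screen$lifespan, file.path(out_dir, "lifespan.csv"), "lifespan")
  write_phenotypes(screen$productivity, file.path(out_dir, "productivity.csv"),
                   "productivity")
  write_phenotypes(screen$qpcr, file.path(out_dir, "qpcr.csv"), "qpcr")
  calls <- stage("screen", call_screen_effects(screen, alpha = alpha))
  utils::write.csv(calls, file.path(out_dir, "effect_calls.csv"),
                   row.names = FALSE)

  profiles <- stage("classify", classify_screen(
    calls, early_weeks = early_weeks, late_weeks = late_weeks))
  utils::write.csv(profiles, file.path(out_dir, "profiles.csv"),
                   row.names = FALSE)

  per_arm <- stage("report", {
    arms <- unique(intervals$arm)
    data.frame(
      arm = arms,
      n_intervals = vapply(arms, function(a)
        sum(intervals$arm == a), integer(1)),
      bp_covered = vapply(arms, function(a)
        sum(intervals$span_bp[intervals$arm == a]), numeric(1)),
      row.names = NULL, stringsAsFactors = FALSE
    )
  })
  report <- list(
    seed = config$seed,
    parameters = list(
      scan = unclass(scan), filter = unclass(filter), alpha = alpha,
      early_weeks = as.integer(early_weeks),
      late_weeks = if (is.null(late_weeks)) "auto(>=4)" else as.integer(late_weeks),
      flank_bp = flank_bp),
    intervals_per_arm = per_arm,
    n_intervals = nrow(intervals),
    total_bp_covered = sum(intervals$span_bp),
    genes_in_intervals = length(interval_gene_ids(intervals)),
    n_candidates = sum(candidates$selected),
    screen_tallies = as.list(summarize_calls(calls)),
    category_tallies = as.list(tally_categories(profiles))
  )
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  writeLines(utils::capture.output(utils::str(report, give.attr = FALSE)),
             file.path(out_dir, "report.txt"))
  invisible(report)
}
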