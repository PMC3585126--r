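#' Run the end-to-end screen pipeline
#'
#' Simulation (or loading) of per-cell records, replicate summarization,
#' deviation-value scoring with region normalization, control-anchored
#' thresholds, effector and hit-gene calling, fingerprints, and a screen
#' report. All randomness flows from the single config seed, split per
#' stage; the run is idempotent for a given config and seed.
#'
#' @param config a `"run_config"` ([read_run_config()]) or a named list
#'   accepted by it.
#' @param layout optional pre-built layout (otherwise simulated from the
#'   config).
#' @param effects optional named list of [effect_spec()]; default null
#'   screen.
#' @param out_dir optional directory; when given, intermediate tables and
#'   the report are written as CSV/JSON.
#' @return list of class `"screen_report"`: `layout`, `summaries`,
#'   `deviations`, `thresholds`, `effector_calls`, `control_calls`,
#'   `gene_calls`, `control_stats`, `provenance`.
#' @export
run_pipeline <- function(config = list(), layout = NULL, effects = list(),
                         out_dir = NULL) {
  cfg <- if (inherits(config, "run_config")) config
    else read_run_config(config)
  scr <- cfg$screen
  if (is.null(layout)) {
    cands <- data.frame(
      sirna_id = sprintf("s%05d", seq_len(scr$n_candidates)),
      gene = paste0("GENE", rep(seq_len(ceiling(scr$n_candidates / 3)),
                                each = 3))[seq_len(scr$n_candidates)])
    layout <- make_plate_layout(scr$format, cands,
                                seed = child_seed(cfg$seed, 1))
  }
  sim <- simulate_screen(layout, effects,
                         n_replicates = scr$n_replicates,
                         assay = scr$assay,
                         images_per_position = scr$images_per_position,
                         tables_only = TRUE,
                         seed = child_seed(cfg$seed, 2))
  summaries <- summarize_replicates(sim$cells, layout)
  scored <- score_deviations(summaries, error = cfg$statistics$error,
                             region_normalize =
                               isTRUE(cfg$statistics$region_normalize))
  ctrl_rep <- scored$replicate_deviations[
    scored$replicate_deviations$role %in% c("negative_control", "mock"), ]
  thresholds <- if (!is.null(cfg$statistics$thresholds))
    cfg$statistics$thresholds else effector_thresholds(ctrl_rep)
  calls <- call_effector_sirnas(scored$deviations, thresholds)
  ctrl_calls <- call_effector_sirnas(scored$deviations, thresholds,
                                     roles = c("negative_control", "mock"))
  gene_map <- unique(layout[layout$role == "candidate",
                            c("sirna_id", "gene")])
  genes <- call_hit_genes(calls, gene_map)
  neg <- scored$deviations[scored$deviations$role == "negative_control" &
                             scored$deviations$parameter == "total", ]
  ctrl_stats <- list(
    n_controls = nrow(neg),
    mean_deviation = mean(neg$mean_deviation),
    normality = tryCatch(
      control_normality_check(neg$mean_deviation, "total")[
        c("statistic", "p_value")],
      error = function(e) NULL))
  report <- structure(list(
    layout = layout, summaries = summaries,
    replicate_deviations = scored$replicate_deviations,
    deviations = scored$deviations, thresholds = thresholds,
    effector_calls = calls, control_calls = ctrl_calls,
    gene_calls = genes, control_stats = ctrl_stats,
    provenance = list(seed = cfg$seed, assay = scr$assay,
                      n_replicates = scr$n_replicates,
                      error = cfg$statistics$error,
                      version = as.character(utils::packageVersion("lipidscreen")))),
    class = "screen_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a screen report to disk
#'
#' Persists the layout, summaries, deviation tables and calls as CSV and
#' the thresholds, control statistics and provenance as JSON.
#'
#' @param report a `"screen_report"`.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the output directory.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("layout", "summaries", "replicate_deviations", "deviations",
               "effector_calls", "control_calls", "gene_calls"))
    write_table_csv(report[[nm]], file.path(out_dir, paste0(nm, ".csv")))
  write_table_csv(report$thresholds, file.path(out_dir, "thresholds.csv"))
  jsonlite::write_json(
    list(control_stats = report$control_stats,
         provenance = report$provenance),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.screen_report <- function(x, ...) {
  n_hit <- sum(x$gene_calls$is_hit)
  n_genes <- nrow(x$gene_calls)
  cat("<screen_report>\n")
  cat(sprintf("  assay: %s, %d replicates, seed %s\n",
              x$provenance$assay, x$provenance$n_replicates,
              x$provenance$seed))
  cat(sprintf("  positions: %d (%d candidates)\n", nrow(x$layout),
              sum(x$layout$role == "candidate")))
  cat(sprintf("  effector siRNAs: %d / %d\n",
              sum(x$effector_calls$direction != "none"),
              nrow(x$effector_calls)))
  cat(sprintf("  hit genes: %d / %d (%s%%)\n", n_hit, n_genes,
              percent_ratio(n_hit, n_genes)))
  invisible(x)
}

#' Headline screen summary rates
#'
#' Recomputes the screen's reporting ratios from counts: a hit rate from
#' hit and tested gene numbers, a screen-to-screen validation rate, a
#' cross-cell-line confirmation rate, and the image QC retention rate,
#' each as an integer percentage (see [percent_ratio()]).
#'
#' @param n_hit_genes,n_genes_tested gene-level counts.
#' @param n_validated,n_effectors_screen1 siRNA validation counts.
#' @param n_confirmed_huh7,n_tested_huh7 cross-cell-line counts.
#' @param n_images_pass,n_images_total image QC counts.
#' @return named list of integer percentages.
#' @export
screen_summary_rates <- function(n_hit_genes, n_genes_tested,
                                 n_validated, n_effectors_screen1,
                                 n_confirmed_huh7, n_tested_huh7,
                                 n_images_pass, n_images_total) {
  list(hit_rate_pct = percent_ratio(n_hit_genes, n_genes_tested),
       validation_rate_pct = percent_ratio(n_validated,
                                           n_effectors_screen1),
       huh7_confirmation_pct = percent_ratio(n_confirmed_huh7,
                                             n_tested_huh7),
       qc_retention_pct = percent_ratio(n_images_pass, n_images_total))
}
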