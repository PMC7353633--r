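# End-to-end orchestration: configuration, the full screening pipeline on a
# survey table, and report writing. The "paper2020" profile reproduces the
# published screening settings.

#' Screening run configuration
#'
#' Collects every tunable of the pipeline with the published screening
#' settings as defaults: 0.5th/99.5th percentile boundaries, variance factor
#' 2, significance 0.01, leave-30\%-out with 100 repetitions, 3-of-4
#' consensus, and the default dose tables.
#'
#' @param seed integer seed for all stochastic steps.
#' @param lower_pct,upper_pct boundary percentiles.
#' @param variance_factor SD multiplier of the variance adjustment.
#' @param alpha significance level for one-class thresholds.
#' @param holdout_fraction,repetitions cross-validation settings.
#' @param min_votes consensus vote threshold.
#' @param knn_k KNN neighbour count used for the screening models.
#' @param dose_levels per-category dose table, see [default_dose_levels].
#' @param profile configuration profile name (`"paper2020"` is the default
#'   full-reproduction profile; any field can still be overridden).
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, lower_pct = 0.5, upper_pct = 99.5,
                       variance_factor = 2, alpha = 0.01,
                       holdout_fraction = 0.30, repetitions = 100,
                       min_votes = 3, knn_k = 3,
                       dose_levels = default_dose_levels(),
                       profile = "paper2020") {
  structure(list(seed = as.integer(seed), lower_pct = lower_pct,
                 upper_pct = upper_pct, variance_factor = variance_factor,
                 alpha = alpha, holdout_fraction = holdout_fraction,
                 repetitions = repetitions, min_votes = min_votes,
                 knn_k = knn_k, dose_levels = dose_levels, profile = profile),
            class = "run_config")
}

#' Screen a market-survey table
#'
#' Runs the full screening pipeline: flags every record against the measured
#' and variance-adjusted boundary sets, builds the four-criteria matrix
#' (univariate flags recomputed from the record values; KNN flags from
#' fitted models or fixture annotations), applies the consensus rule, and
#' aggregates per-area prevalence.
#'
#' @param records survey composition table.
#' @param boundaries list with `measured` and `variance_adjusted`
#'   [boundary_set]s (default: the bundled control-set boundaries).
#' @param knn_models optional list with `measured` and `variance_adjusted`
#'   fitted `occ_model`s; when `NULL`, `annotations` supply the KNN flags.
#' @param annotations annotation table (see [load_table3_fixture]).
#' @param area_totals per-area denominators (default: the bundled survey
#'   totals).
#' @param config a [run_config].
#' @return list of class `screen_report`: `violations_measured`,
#'   `violations_varadj` (from [count_flagged]), `criteria`, `suspects`
#'   (data.frame with `sample_id`, `area`), `prevalence`.
#' @export
screen_survey <- function(records,
                          boundaries = load_table1_fixture()$boundaries,
                          knn_models = NULL, annotations = NULL,
                          area_totals = load_area_totals(),
                          config = run_config()) {
  validate_records(records, closure_tol = Inf)
  if (nrow(records) == 0L) {
    empty <- count_flagged(records, boundaries$measured)
    return(structure(list(violations_measured = empty,
                          violations_varadj = empty,
                          criteria = NULL,
                          suspects = records[0, c("sample_id", "area")],
                          prevalence = prevalence_by_area(
                            data.frame(sample_id = character(0),
                                       area = character(0)),
                            area_totals)),
                     class = "screen_report"))
  }
  vm <- count_flagged(records, boundaries$measured)
  vv <- count_flagged(records, boundaries$variance_adjusted)
  crit <- build_criteria(records, boundaries$measured,
                         boundaries$variance_adjusted,
                         knn_measured = knn_models$measured,
                         knn_varadj = knn_models$variance_adjusted,
                         annotations = annotations)
  susp_ids <- consensus(crit, min_votes = config$min_votes)
  ids <- as.character(records$sample_id)
  suspects <- data.frame(sample_id = susp_ids,
                         area = records$area[match(susp_ids, ids)],
                         stringsAsFactors = FALSE)
  prev <- prevalence_by_area(suspects, area_totals)
  structure(list(violations_measured = vm, violations_varadj = vv,
                 criteria = crit, suspects = suspects, prevalence = prev),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("Milk screening report\n")
  cat(sprintf("  flagged by measured boundaries:          %d\n",
              x$violations_measured$n_flagged))
  cat(sprintf("  flagged by variance-adjusted boundaries: %d\n",
              x$violations_varadj$n_flagged))
  if (!is.null(x$criteria)) {
    cat(sprintf("  flagged by any criterion:                %d\n",
                sum(x$criteria$vote >= 1)))
  }
  cat(sprintf("  consensus suspects:                      %d (%s)\n",
              nrow(x$suspects), paste(x$suspects$sample_id, collapse = ", ")))
  cat("  prevalence by area:\n")
  p <- x$prevalence
  for (i in seq_len(nrow(p))) {
    cat(sprintf("    %-3s %2d/%2d  %d%%\n", p$area[i], p$n_suspected[i],
                p$n_total[i], p$pct_display[i]))
  }
  invisible(x)
}

#' Write a screening report bundle to disk
#'
#' Violation reports and the criteria matrix as CSV, suspects and prevalence
#' as both CSV and JSON.
#'
#' @param report a `screen_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_screen_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$violations_measured$report,
                   file.path(dir, "violations_measured.csv"), row.names = FALSE)
  utils::write.csv(report$violations_varadj$report,
                   file.path(dir, "violations_varadj.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$criteria),
                   file.path(dir, "criteria.csv"), row.names = FALSE)
  utils::write.csv(report$suspects, file.path(dir, "suspects.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(report$prevalence),
                   file.path(dir, "prevalence.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(suspects = report$suspects$sample_id,
         prevalence = as.data.frame(report$prevalence)),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
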