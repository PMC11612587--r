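#' Run the full analysis pipeline
#'
#' Orchestrates cohort generation (or loading), per-trial metric extraction,
#' outlier screening, factorial inference, condition summaries, and
#' questionnaire descriptives into one reproducible run. All artifacts are
#' written under `out_dir`; identical config + seed yields byte-identical
#' outputs. Every observation excluded anywhere is accounted for in the run
#' log (input rows = analyzed rows + excluded rows, per metric).
#'
#' @param config A [cohort_config()] driving the generator (ignored for the
#'   cohort itself when `input_dir` is given).
#' @param out_dir Output directory (created if needed).
#' @param input_dir Optional directory with an existing cohort (written by
#'   [write_cohort()]); when given, logs are read instead of simulated.
#' @param alpha Significance level recorded with the effect tables.
#' @param remove_outliers Apply the per-cell 1.5 IQR screen (default TRUE).
#' @param write_trial_logs Also write the raw trial log CSVs (default FALSE;
#'   they are bulky).
#' @return Invisible list: `metrics`, `analysis` (see [analyze_metrics()]),
#'   `questionnaire_summary`, `files` (paths written).
#' @export
run_pipeline <- function(config = cohort_config(), out_dir,
                         input_dir = NULL, alpha = 0.05,
                         remove_outliers = TRUE, write_trial_logs = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- if (is.null(input_dir)) generate_cohort(config)
            else read_cohort(input_dir, sampling_rate = config$sampling_rate)
  if (isTRUE(write_trial_logs) && is.null(input_dir)) {
    write_cohort(cohort, file.path(out_dir, "cohort"))
  }

  metrics <- compute_metrics_table(cohort,
                                   sampling_rate = config$sampling_rate)
  analysis <- analyze_metrics(metrics, remove_outliers = remove_outliers)
  qsum <- if (!is.null(cohort$questionnaire)) {
    summarize_questionnaire(cohort$questionnaire)
  }

  files <- c(
    metrics = file.path(out_dir, "metrics.csv"),
    effects = file.path(out_dir, "effects.csv"),
    outliers = file.path(out_dir, "outliers.csv"),
    summaries = file.path(out_dir, "condition_summaries.csv"),
    config = file.path(out_dir, "config.yaml"),
    log = file.path(out_dir, "run_log.txt")
  )
  write_metrics_table(metrics, files[["metrics"]])
  readr::write_csv(analysis$effects, files[["effects"]], progress = FALSE)
  readr::write_csv(analysis$outliers, files[["outliers"]], progress = FALSE)
  readr::write_csv(analysis$summaries, files[["summaries"]], progress = FALSE)
  if (!is.null(qsum)) {
    files[["questionnaire"]] <- file.path(out_dir, "questionnaire_summary.csv")
    readr::write_csv(qsum, files[["questionnaire"]], progress = FALSE)
  }
  plot_data <- export_interaction_plot_data(analysis$summaries)
  for (m in names(plot_data)) {
    f <- file.path(out_dir, paste0("interaction_", m, ".csv"))
    files[[paste0("interaction_", m)]] <- f
    readr::write_csv(plot_data[[m]], f, progress = FALSE)
  }

  yaml::write_yaml(config_to_list(config), files[["config"]])
  log_lines <- c(
    paste0("config_md5: ", unname(tools::md5sum(files[["config"]]))),
    paste0("seed: ", config$seed),
    paste0("alpha: ", alpha),
    paste0("trials_simulated: ", length(cohort$trials)),
    paste0("metric_rows: ", nrow(metrics)),
    vapply(analysis$outliers$metric, function(m) {
      excl <- analysis$outliers$count[analysis$outliers$metric == m]
      paste0(m, ": input=", analysis$n_input,
             " analyzed=", analysis$n_analyzed[[m]],
             " excluded=", excl)
    }, character(1))
  )
  writeLines(log_lines, files[["log"]])

  invisible(list(metrics = metrics, analysis = analysis,
                 questionnaire_summary = qsum, files = files))
}

config_to_list <- function(config) {
  out <- unclass(config)
  out$obstacle_layout <- as.data.frame(out$obstacle_layout)
  out
}

#' Interaction-plot data per metric
#'
#' Reshapes condition summaries into one tidy 2x2 cell-mean table per metric
#' (mean, SEM, n per haptic x audio cell), the data behind the standard
#' factorial interaction plot.
#'
#' @param summaries Output of [condition_summaries()] (long tibble).
#' @return Named list of per-metric tibbles.
#' @export
export_interaction_plot_data <- function(summaries) {
  split(
    summaries[, c("metric", "haptic", "audio", "mean", "sem", "n")],
    summaries$metric
  )
}

#' Interaction plot for one metric
#'
#' Cell means with SEM error bars, haptic on the x axis, one line per audio
#' level. Cells whose SEM is undefined (single observation) are drawn
#' without an error bar.
#'
#' @param summaries Output of [condition_summaries()].
#' @param metric Metric to plot.
#' @return A ggplot object.
#' @export
plot_interaction <- function(summaries, metric) {
  d <- summaries[summaries$metric == metric, ]
  if (nrow(d) == 0) stop("no summaries for metric ", metric, call. = FALSE)
  d$haptic_lab <- ifelse(d$haptic, "haptic on", "haptic off")
  d$audio_lab <- ifelse(d$audio, "audio on", "audio off")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$haptic_lab, y = .data$mean,
                                  group = .data$audio_lab,
                                  colour = .data$audio_lab)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      data = d[!is.na(d$sem), ],
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      width = 0.1
    ) +
    ggplot2::labs(x = NULL, y = metric, colour = NULL) +
    ggplot2::theme_minimal()
}
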