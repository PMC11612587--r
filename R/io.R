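# Canonical CSV schemas. Units on disk: seconds, meters, degrees; comma
# separated, dot decimal, UTF-8, header row mandatory.

TRIAL_LOG_COLUMNS <- c("t", "x", "y", "z", "head_yaw", "head_pitch",
                       "head_roll", "body_yaw", "body_pitch", "body_roll",
                       "collision")
MANIFEST_COLUMNS <- c("participant_id", "haptic", "audio", "order_index",
                      "log_path")

QUESTIONNAIRE_LEVELS <- list(
  q1_vr_experience = c("yes", "no"),
  q2_engaged = c("yes", "no"),
  q3_motion_sickness = c("yes", "no"),
  q4_best_performance_condition = c("none", "haptic", "audio", "both",
                                    "unsure"),
  q6_preferred_condition = c("none", "haptic", "audio", "both", "unsure"),
  q8_interest = c("not_at_all", "slightly", "moderately", "fairly",
                  "extremely")
)

#' Read a trial telemetry log
#'
#' Expects the canonical trial-log CSV (columns `t, x, y, z, head_yaw,
#' head_pitch, head_roll, body_yaw, body_pitch, body_roll, collision`;
#' seconds, meters, degrees). Time stamps must be strictly increasing and
#' positions must be finite.
#'
#' @param path Path to the CSV file.
#' @return Trial log tibble, rows in time order, `collision` logical.
#' @export
read_trial_log <- function(path) {
  if (!file.exists(path)) stop("trial log not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(TRIAL_LOG_COLUMNS, names(df))
  if (length(missing)) {
    stop("trial log ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[TRIAL_LOG_COLUMNS]
  bad <- which(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z))
  if (length(bad)) {
    stop("non-finite position in trial log ", path, " at row ", bad[1],
         call. = FALSE)
  }
  nonmono <- which(diff(df$t) <= 0)
  if (length(nonmono)) {
    stop("time stamps not strictly increasing in ", path, " at row ",
         nonmono[1] + 1, call. = FALSE)
  }
  df$collision <- as.logical(df$collision)
  df
}

#' Write a trial telemetry log
#'
#' @param trial Trial log tibble with the canonical columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(trial, path) {
  stopifnot(all(TRIAL_LOG_COLUMNS %in% names(trial)))
  readr::write_csv(trial[TRIAL_LOG_COLUMNS], path, progress = FALSE)
  invisible(path)
}

#' Read a cohort manifest
#'
#' @param path Manifest CSV (columns `participant_id, haptic, audio,
#'   order_index, log_path`). Duplicate (participant, condition) rows are an
#'   error.
#' @return Manifest tibble.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(MANIFEST_COLUMNS, names(df))
  if (length(missing)) {
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(df$participant_id, df$haptic, df$audio)
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), ]
    stop("duplicate manifest row for participant ", dup$participant_id[1],
         " (haptic=", dup$haptic[1], ", audio=", dup$audio[1], ")",
         call. = FALSE)
  }
  df[MANIFEST_COLUMNS]
}

#' @rdname read_manifest
#' @param manifest Manifest tibble.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(all(MANIFEST_COLUMNS %in% names(manifest)))
  readr::write_csv(manifest[MANIFEST_COLUMNS], path, progress = FALSE)
  invisible(path)
}

#' Read/write a per-trial metrics table
#'
#' Symmetric, lossless contracts: `read_metrics_table(write_metrics_table(x))`
#' reproduces `x`.
#'
#' @param records Metrics tibble (one row per participant x condition).
#' @param path CSV path.
#' @return The written path (write) or the metrics tibble (read).
#' @export
write_metrics_table <- function(records, path) {
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_metrics_table
#' @export
read_metrics_table <- function(path) {
  if (!file.exists(path)) stop("metrics table not found: ", path, call. = FALSE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read a questionnaire table
#'
#' Validates the closed-category items against their allowed levels; an
#' unknown category value is an error naming the row and column. Free-text
#' items (q5, q7) pass through untouched.
#'
#' @param path Questionnaire CSV, one row per participant.
#' @return Questionnaire tibble.
#' @export
read_questionnaire <- function(path) {
  if (!file.exists(path)) stop("questionnaire not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_questionnaire(df)
}

#' @rdname read_questionnaire
#' @param table Questionnaire tibble.
#' @export
write_questionnaire <- function(table, path) {
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

validate_questionnaire <- function(df) {
  if (!"participant_id" %in% names(df)) {
    stop("questionnaire is missing column participant_id", call. = FALSE)
  }
  if (anyDuplicated(df$participant_id)) {
    stop("duplicate participant_id in questionnaire: ",
         df$participant_id[duplicated(df$participant_id)][1], call. = FALSE)
  }
  for (col in intersect(names(QUESTIONNAIRE_LEVELS), names(df))) {
    bad <- which(!df[[col]] %in% QUESTIONNAIRE_LEVELS[[col]])
    if (length(bad)) {
      stop("unknown category '", df[[col]][bad[1]], "' in column ", col,
           " at row ", bad[1], call. = FALSE)
    }
  }
  df
}

#' Write a generated cohort to disk
#'
#' Lays out the cohort as `manifest.csv`, `questionnaire.csv`, and one trial
#' log CSV per trial under `trials/`, with manifest paths relative to `dir`.
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "trials"), recursive = TRUE, showWarnings = FALSE)
  write_manifest(cohort$manifest, file.path(dir, "manifest.csv"))
  write_questionnaire(cohort$questionnaire, file.path(dir, "questionnaire.csv"))
  for (i in seq_len(nrow(cohort$manifest))) {
    row <- cohort$manifest[i, ]
    key <- sub("\\.csv$", "", basename(row$log_path))
    write_trial_log(cohort$trials[[key]], file.path(dir, row$log_path))
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Cohort directory containing `manifest.csv`.
#' @param sampling_rate Sampling rate of the logs in Hz (stored in the
#'   returned pseudo-config for downstream metric extraction).
#' @return List with `trials`, `manifest`, `questionnaire` (if present), and
#'   a minimal `config` carrying the sampling rate.
#' @export
read_cohort <- function(dir, sampling_rate = 72) {
  manifest <- read_manifest(file.path(dir, "manifest.csv"))
  trials <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    path <- file.path(dir, row$log_path)
    if (!file.exists(path)) {
      stop("manifest refers to a missing log file: ", path, call. = FALSE)
    }
    trial <- read_trial_log(path)
    attr(trial, "participant_id") <- row$participant_id
    attr(trial, "haptic") <- row$haptic
    attr(trial, "audio") <- row$audio
    trials[[sub("\\.csv$", "", basename(row$log_path))]] <- trial
  }
  qpath <- file.path(dir, "questionnaire.csv")
  list(
    trials = trials,
    manifest = manifest,
    questionnaire = if (file.exists(qpath)) read_questionnaire(qpath),
    config = list(sampling_rate = sampling_rate)
  )
}
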