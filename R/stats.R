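#' Flag outliers with the 1.5 IQR boxplot rule
#'
#' An observation is flagged when it falls outside
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, with quartiles by linear interpolation
#' (type 7), computed within its haptic x audio condition cell (default) or
#' pooled over the whole metric column. Flagged rows are meant to be excluded
#' from subsequent model fits for that metric only (per-metric listwise
#' removal).
#'
#' @param data Metrics tibble with logical `haptic`, `audio` columns.
#' @param metric Name of the metric column to screen.
#' @param per_cell Screen within condition cells (default) or pooled.
#' @return List of class `outlier_report`: `metric`, `flags` (logical vector
#'   aligned with `data` rows), `flagged` (tibble of flagged rows), `count`,
#'   `percentage` (of all observations).
#' @export
flag_outliers <- function(data, metric, per_cell = TRUE) {
  v <- data[[metric]]
  if (is.null(v) || length(v) == 0) {
    stop("empty metric column: ", metric, call. = FALSE)
  }
  cell <- if (per_cell) paste(data$haptic, data$audio) else rep("all", nrow(data))
  flags <- logical(length(v))
  for (g in unique(cell)) {
    idx <- which(cell == g)
    q <- quantile(v[idx], c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    flags[idx] <- v[idx] < q[1] - 1.5 * iqr | v[idx] > q[2] + 1.5 * iqr
  }
  structure(
    list(
      metric = metric,
      flags = flags,
      flagged = data[flags, intersect(c("participant_id", "haptic", "audio",
                                        metric), names(data))],
      count = sum(flags),
      percentage = 100 * sum(flags) / length(v)
    ),
    class = "outlier_report"
  )
}

#' Mid-rank transformation
#'
#' Ranks 1..N with tied values sharing the mean of their covered ranks, so
#' the rank sum is always N(N+1)/2.
#'
#' @param values Numeric vector without NAs.
#' @return Numeric vector of (mid-)ranks.
#' @export
rank_transform <- function(values) {
  if (length(values) < 1) stop("empty input", call. = FALSE)
  if (anyNA(values)) stop("NA values cannot be ranked", call. = FALSE)
  rank(values, ties.method = "average")
}

check_factors <- function(data) {
  for (f in c("haptic", "audio")) {
    if (length(unique(data[[f]])) < 2) {
      stop("factor '", f, "' has only one observed level", call. = FALSE)
    }
  }
}

#' Two-way repeated-measures ANOVA via a mixed model
#'
#' Fits `metric ~ haptic * audio + (1 | participant_id)` with
#' [lmerTest::lmer()] to the (possibly unbalanced, outlier-screened) data and
#' returns per-effect F statistics with Satterthwaite approximate denominator
#' degrees of freedom. On balanced data with no between-participant variance
#' the F statistics coincide with the classical two-way fixed-effects ANOVA.
#'
#' @param data Metrics tibble with `participant_id`, logical `haptic` and
#'   `audio`, and the metric column.
#' @param metric Name of the continuous response column.
#' @return Effect-table tibble with one row per effect (haptic, audio,
#'   interaction): metric, effect, statistic_kind ("F"), statistic, df1, df2
#'   (fractional Satterthwaite), p_value.
#' @export
rm_anova <- function(data, metric) {
  check_factors(data)
  if (length(unique(data$participant_id)) < 2) {
    stop("need at least 2 participants", call. = FALSE)
  }
  d <- data.frame(
    y = data[[metric]],
    haptic = factor(data$haptic),
    audio = factor(data$audio),
    participant_id = factor(data$participant_id)
  )
  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(
      y ~ haptic * audio + (1 | participant_id), data = d,
      control = lme4::lmerControl(check.conv.singular = "ignore")
    )),
    error = function(e) {
      stop("mixed-model fit failed for '", metric, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  at <- stats::anova(fit, type = 3)
  rows <- c("haptic", "audio", "haptic:audio")
  tibble::tibble(
    metric = metric,
    effect = c("haptic", "audio", "interaction"),
    statistic_kind = "F",
    statistic = at[rows, "F value"],
    df1 = at[rows, "NumDF"],
    df2 = at[rows, "DenDF"],
    p_value = at[rows, "Pr(>F)"]
  )
}

#' Scheirer-Ray-Hare rank test for a two-way factorial design
#'
#' Rank-based extension of the Kruskal-Wallis test: all N observations are
#' mid-ranked, factorial sums of squares are computed on the ranks, and each
#' effect's statistic is `H = SS_effect / MS_total` with
#' `MS_total = SS_total / (N - 1)`, corrected for ties by dividing by
#' `D = 1 - sum(t^3 - t) / (N^3 - N)` over tie groups of size t. P-values
#' come from the chi-square upper tail with the effect's degrees of freedom.
#' The statistic is invariant under strictly monotone transforms of the
#' response. When all observations are tied, every H is 0 and p is 1.
#'
#' @param data Metrics tibble with logical `haptic`, `audio` columns; every
#'   cell of the 2x2 grid must be observed.
#' @param metric Name of the (discrete) response column, default
#'   `"n_collisions"`.
#' @param tie_correction Apply the tie correction (default TRUE).
#' @return Effect-table tibble (metric, effect, statistic_kind "H",
#'   statistic, df1, df2 = NA, p_value).
#' @export
scheirer_ray_hare <- function(data, metric = "n_collisions",
                              tie_correction = TRUE) {
  check_factors(data)
  cells <- table(data$haptic, data$audio)
  if (any(cells == 0)) stop("empty condition cell", call. = FALSE)
  y <- data[[metric]]
  if (anyNA(y)) stop("NA values in ", metric, call. = FALSE)
  n <- length(y)
  r <- rank_transform(y)
  ss_total <- sum((r - mean(r))^2)
  if (ss_total == 0) {
    return(tibble::tibble(
      metric = metric,
      effect = c("haptic", "audio", "interaction"),
      statistic_kind = "H", statistic = 0, df1 = 1, df2 = NA_real_,
      p_value = 1
    ))
  }
  d <- data.frame(r = r, haptic = factor(data$haptic),
                  audio = factor(data$audio))
  # type II SS: equals the classical decomposition on balanced data, well
  # defined under the mild unbalance left by outlier removal
  at <- car::Anova(stats::lm(r ~ haptic * audio, data = d), type = 2)
  rows <- c("haptic", "audio", "haptic:audio")
  ss <- at[rows, "Sum Sq"]
  df <- at[rows, "Df"]
  ms_total <- ss_total / (n - 1)
  h <- ss / ms_total
  if (tie_correction) {
    t_sizes <- table(y)
    correction <- 1 - sum(t_sizes^3 - t_sizes) / (n^3 - n)
    h <- h / correction
  }
  tibble::tibble(
    metric = metric,
    effect = c("haptic", "audio", "interaction"),
    statistic_kind = "H",
    statistic = as.numeric(h),
    df1 = as.numeric(df),
    df2 = NA_real_,
    p_value = pchisq(as.numeric(h), df, lower.tail = FALSE)
  )
}

#' Per-cell condition summaries (mean, SEM, n)
#'
#' @param data Metrics tibble.
#' @param metrics Metric columns to summarize; defaults to the six standard
#'   metrics present in `data`.
#' @return Long tibble: metric, haptic, audio, mean, sem (NA for
#'   single-observation cells), n. Input row order is irrelevant.
#' @export
condition_summaries <- function(data, metrics = intersect(METRIC_NAMES,
                                                          names(data))) {
  out <- lapply(metrics, function(m) {
    data |>
      dplyr::group_by(.data$haptic, .data$audio) |>
      dplyr::summarise(
        mean = mean(.data[[m]]),
        sem = if (dplyr::n() > 1) sd(.data[[m]]) / sqrt(dplyr::n())
              else NA_real_,
        n = dplyr::n(),
        .groups = "drop"
      ) |>
      dplyr::mutate(metric = m, .before = 1)
  })
  dplyr::bind_rows(out)
}

#' Full inferential analysis of a metrics table
#'
#' Screens each metric for outliers (per-cell 1.5 IQR rule, per-metric
#' listwise removal), then runs the two-way repeated-measures mixed ANOVA on
#' the continuous metrics (completion time, L, rank-transformed SPARC,
#' H_pitch, H_chi) and the Scheirer-Ray-Hare test on collision counts.
#'
#' @param metrics Metrics tibble (one row per participant x condition).
#' @param remove_outliers Apply the outlier screen (default TRUE).
#' @param per_cell Outlier screening within condition cells (default TRUE).
#' @return List: `effects` (combined effect table), `outliers` (tibble:
#'   metric, count, percentage), `summaries` (post-screen condition
#'   summaries per metric), `n_input`, `n_analyzed` (named per metric).
#' @export
analyze_metrics <- function(metrics, remove_outliers = TRUE,
                            per_cell = TRUE) {
  present <- intersect(METRIC_NAMES, names(metrics))
  reports <- lapply(present, function(m) {
    if (remove_outliers) flag_outliers(metrics, m, per_cell = per_cell)
    else list(metric = m, flags = logical(nrow(metrics)), count = 0,
              percentage = 0)
  })
  names(reports) <- present

  effects <- list()
  summaries <- list()
  n_analyzed <- integer()
  for (m in present) {
    keep <- !reports[[m]]$flags
    d <- metrics[keep, ]
    n_analyzed[m] <- nrow(d)
    if (m == "n_collisions") {
      effects[[m]] <- scheirer_ray_hare(d, m)
    } else if (m == "SPARC") {
      d$SPARC_rank <- rank_transform(d$SPARC)
      eff <- rm_anova(d, "SPARC_rank")
      eff$metric <- "SPARC"
      effects[[m]] <- eff
    } else {
      effects[[m]] <- rm_anova(d, m)
    }
    summaries[[m]] <- condition_summaries(d, m)
  }
  list(
    effects = dplyr::bind_rows(effects),
    outliers = tibble::tibble(
      metric = present,
      count = vapply(reports, function(r) as.integer(r$count), integer(1),
                     USE.NAMES = FALSE),
      percentage = vapply(reports, function(r) as.numeric(r$percentage),
                          numeric(1), USE.NAMES = FALSE)
    ),
    outlier_reports = reports,
    summaries = dplyr::bind_rows(summaries),
    n_input = nrow(metrics),
    n_analyzed = n_analyzed
  )
}
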