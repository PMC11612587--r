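#' Round a proportion to the nearest integer percent
#'
#' Half-up rounding (`floor(x + 0.5)`), the convention used in reporting
#' survey percentages (e.g. 45/72 = 62.5% reports as 63%), as opposed to R's
#' round-half-even.
#'
#' @param count Category count(s).
#' @param n Denominator.
#' @return Integer percentage(s) in 0..100.
#' @export
percent_round <- function(count, n) {
  as.integer(floor(100 * count / n + 0.5))
}

#' Descriptive summary of a questionnaire table
#'
#' Per closed item and category: count, denominator, exact fraction, and the
#' integer percentage (half-up rounding). Categories with zero answers are
#' retained with count 0. Free-text items (q5, q7) are not summarized.
#'
#' @param table Questionnaire tibble (validated closed categories; see
#'   [read_questionnaire()]).
#' @return Tibble: item, category, count, denominator, fraction, percentage.
#' @export
summarize_questionnaire <- function(table) {
  table <- validate_questionnaire(table)
  n <- nrow(table)
  out <- lapply(names(QUESTIONNAIRE_LEVELS), function(item) {
    if (!item %in% names(table)) return(NULL)
    levels <- QUESTIONNAIRE_LEVELS[[item]]
    counts <- table(factor(table[[item]], levels = levels))
    tibble::tibble(
      item = item,
      category = levels,
      count = as.integer(counts),
      denominator = n,
      fraction = as.integer(counts) / n,
      percentage = percent_round(as.integer(counts), n)
    )
  })
  dplyr::bind_rows(out)
}

#' Build a questionnaire table from per-item category counts
#'
#' Deterministic helper for exercising the summary module with known counts
#' (e.g. published category tallies): row i of the output carries, for each
#' item, the category whose cumulative count covers i. Counts per item must
#' sum to `n`.
#'
#' @param n Number of participants.
#' @param counts Named list; each element a named integer vector of category
#'   counts for one closed item.
#' @return Questionnaire tibble with one row per participant.
#' @export
questionnaire_from_counts <- function(n, counts) {
  tbl <- tibble::tibble(participant_id = sprintf("P%02d", seq_len(n)))
  for (item in names(counts)) {
    if (!item %in% names(QUESTIONNAIRE_LEVELS)) {
      stop("unknown questionnaire item: ", item, call. = FALSE)
    }
    v <- counts[[item]]
    if (sum(v) != n) {
      stop("counts for ", item, " sum to ", sum(v), ", expected ", n,
           call. = FALSE)
    }
    bad <- setdiff(names(v), QUESTIONNAIRE_LEVELS[[item]])
    if (length(bad)) {
      stop("unknown category '", bad[1], "' for item ", item, call. = FALSE)
    }
    tbl[[item]] <- rep(names(v), times = v)
  }
  tbl
}
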