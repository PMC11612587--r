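test_that("percent rounding is half-up to the nearest integer", {
  expect_equal(percent_round(29, 72), 40L)  # 40.28 -> 40
  expect_equal(percent_round(36, 72), 50L)
  expect_equal(percent_round(45, 72), 63L)  # 62.5 rounds up, not to even
  expect_equal(percent_round(0, 72), 0L)
  expect_equal(percent_round(72, 72), 100L)
})

test_that("summaries reproduce known category tallies", {
  tbl <- questionnaire_from_counts(72, list(
    q6_preferred_condition = c(both = 29, audio = 23, haptic = 13, none = 4,
                               unsure = 3)
  ))
  s <- summarize_questionnaire(tbl)
  get <- function(cat) s$percentage[s$category == cat]
  expect_equal(get("both"), 40L)
  expect_equal(get("audio"), 32L)
  expect_equal(get("haptic"), 18L)
  expect_equal(s$count[s$category == "both"], 29L)
  expect_equal(unique(s$denominator), 72L)
  # zero-count categories are retained at 0%
  tbl2 <- questionnaire_from_counts(72, list(
    q3_motion_sickness = c(yes = 0, no = 72)
  ))
  s2 <- summarize_questionnaire(tbl2)
  expect_equal(s2$percentage[s2$category == "yes"], 0L)
})

test_that("percentages of a partition sum to 100 within rounding slack", {
  set.seed(4)
  for (i in 1:10) {
    q <- generate_questionnaire(72)
    s <- summarize_questionnaire(q)
    for (item in unique(s$item)) {
      si <- s[s$item == item, ]
      expect_equal(sum(si$count), 72)
      expect_lte(abs(sum(si$percentage) - 100), nrow(si) / 2)
    }
  }
})

test_that("summaries are independent of row order", {
  set.seed(6)
  q <- generate_questionnaire(30)
  s1 <- summarize_questionnaire(q)
  s2 <- summarize_questionnaire(q[sample(nrow(q)), ])
  expect_equal(s1, s2)
})

test_that("count builders validate items, categories, and totals", {
  expect_error(questionnaire_from_counts(72, list(q9_x = c(yes = 72))),
               "q9_x")
  expect_error(
    questionnaire_from_counts(72, list(q1_vr_experience = c(maybe = 72))),
    "maybe"
  )
  expect_error(
    questionnaire_from_counts(72, list(q1_vr_experience = c(yes = 10, no = 10))),
    "sum to 20"
  )
})
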