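test_that("cohort cardinality is forced by the 2x2 within-subject design", {
  cfg <- fast_config(n = 2, seed = 7)
  co <- generate_cohort(cfg)
  expect_length(co$trials, 8)
  expect_equal(nrow(co$manifest), 8)
  expect_equal(nrow(co$questionnaire), 2)
  # each participant holds every condition cell exactly once
  per <- table(co$manifest$participant_id,
               paste(co$manifest$haptic, co$manifest$audio))
  expect_true(all(per == 1))
  expect_setequal(co$manifest$order_index, 1:4)
})

test_that("identical config and seed regenerate identical cohorts", {
  cfg <- fast_config(n = 2, seed = 3)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$questionnaire, c2$questionnaire)
  for (k in names(c1$trials)) {
    expect_identical(c1$trials[[k]], c2$trials[[k]], label = k)
  }
})

test_that("a zero-noise walker in an empty corridor walks straight", {
  wk <- default_walker_params()
  wk$sigma_heading[] <- 0
  wk$sigma_speed[] <- 0
  wk$hesitation_rate <- 0
  cfg <- cohort_config(
    n_participants = 2, course_length = 16,
    obstacle_layout = tibble::tibble(x = numeric(), y = numeric(),
                                     radius = numeric()),
    walker = wk, seed = 1
  )
  set.seed(1)
  tr <- simulate_trial(condition = "none", config = cfg)
  expect_equal(collision_count(tr), 0)
  expect_false(attr(tr, "incomplete"))
  # timestamps strictly increasing at 1/sampling_rate spacing
  expect_equal(diff(tr$t), rep(1 / cfg$sampling_rate, nrow(tr) - 1))
  # outbound leg tracks the corridor midline
  out_leg <- tr$x[tr$t < 6]
  expect_lt(max(abs(out_leg)), 0.05)
  # all angles within (-180, 180]
  for (col in c("head_yaw", "body_yaw")) {
    expect_true(all(tr[[col]] > -180 & tr[[col]] <= 180))
  }
})

test_that("detection geometry controls collisions with an on-path obstacle", {
  wk <- default_walker_params()
  wk$sigma_heading[] <- 0
  wk$sigma_speed[] <- 0
  wk$hesitation_rate <- 0
  obs <- tibble::tibble(x = 0, y = 5, radius = 0.35)
  cfg <- cohort_config(n_participants = 2, course_length = 16,
                       obstacle_layout = obs, walker = wk, seed = 1)
  set.seed(1)
  # belt-style detection at 2.5 m with the default gain clears the obstacle
  expect_equal(collision_count(simulate_trial(condition = "haptic",
                                              config = cfg)), 0)
  # detection disabled: the walker ploughs straight through
  wk_blind <- wk
  wk_blind$avoid_gain[] <- 0
  cfg_blind <- cohort_config(n_participants = 2, course_length = 16,
                             obstacle_layout = obs, walker = wk_blind,
                             seed = 1)
  set.seed(1)
  expect_gte(collision_count(simulate_trial(condition = "none",
                                            config = cfg_blind)), 1)
})

test_that("unknown effect-size keys are rejected by name", {
  expect_error(cohort_config(effect_sizes = list(sparkle = c(haptic = 1))),
               "sparkle")
  expect_error(
    cohort_config(effect_sizes = list(SPARC = c(vibration = 1))),
    "vibration"
  )
  expect_error(cohort_config(n_participants = 1), "at least 2")
})

test_that("programmed directions realize in generated cohorts", {
  # metrics-level replicates: every programmed sign, many cohorts
  set.seed(31)
  ok <- replicate(30, all(direction_checks(
    simulate_metrics_cohort(cohort_config(n_participants = 72), seed = NULL)
  )))
  expect_gte(mean(ok), 0.95)
  # one full telemetry cohort end to end
  m <- compute_metrics_table(generate_cohort(cohort_config(
    n_participants = 16, seed = 5
  )))
  expect_true(all(direction_checks(m)))
})

test_that("trials that cannot finish are flagged incomplete and excluded", {
  wk <- default_walker_params()
  wk$max_duration <- 3   # far too short to finish the course
  cfg <- fast_config(n = 2, seed = 2, walker = wk)
  set.seed(1)
  expect_warning(tr <- simulate_trial(condition = "none", config = cfg),
                 "incomplete")
  expect_true(attr(tr, "incomplete"))
  suppressWarnings(co <- generate_cohort(cfg))
  expect_warning(m <- compute_metrics_table(co), "excluded")
  expect_equal(nrow(m), 0)
})
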