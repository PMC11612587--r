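make_cells <- function(values_by_cell) {
  grid <- condition_grid()
  dplyr::bind_rows(lapply(1:4, function(i) {
    v <- values_by_cell[[i]]
    tibble::tibble(
      participant_id = sprintf("P%02d", seq_along(v)),
      haptic = grid$haptic[i], audio = grid$audio[i], value = v
    )
  }))
}

test_that("IQR rule flags the textbook cases", {
  d <- make_cells(list(c(1, 2, 3, 4, 100), c(1, 2, 3, 4, 5),
                       c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5)))
  rep <- flag_outliers(d, "value")
  expect_equal(d$value[rep$flags], 100)
  expect_equal(rep$count, 1)
  expect_equal(rep$percentage, 100 / 20)

  all_eq <- make_cells(replicate(4, rep(7, 6), simplify = FALSE))
  expect_equal(flag_outliers(all_eq, "value")$count, 0)
  expect_error(flag_outliers(all_eq, "nope"), "empty metric")
})

test_that("IQR flags match a brute-force quartile-rule recomputation", {
  set.seed(99)
  d <- make_cells(replicate(4, rnorm(72), simplify = FALSE))
  rep <- flag_outliers(d, "value")
  brute <- logical(nrow(d))
  for (i in seq_len(nrow(d))) {
    idx <- d$haptic == d$haptic[i] & d$audio == d$audio[i]
    v <- sort(d$value[idx])
    # type-7 quartiles by explicit interpolation
    qt <- function(p) {
      h <- (length(v) - 1) * p
      v[floor(h) + 1] + (h - floor(h)) * (v[floor(h) + 2 - (h == floor(h))] -
                                            v[floor(h) + 1])
    }
    q1 <- qt(0.25); q3 <- qt(0.75); iqr <- q3 - q1
    brute[i] <- d$value[i] < q1 - 1.5 * iqr | d$value[i] > q3 + 1.5 * iqr
  }
  expect_identical(rep$flags, brute)
})

test_that("mid-ranks follow the textbook definition", {
  expect_equal(rank_transform(c(10, 20, 20, 30)), c(1, 2.5, 2.5, 4))
  expect_equal(rank_transform(c(3, 8, 9, 15)), 1:4, ignore_attr = TRUE)
  set.seed(2)
  for (v in list(rnorm(50), rpois(30, 2), rep(1, 9))) {
    n <- length(v)
    expect_equal(sum(rank_transform(v)), n * (n + 1) / 2)
  }
  expect_error(rank_transform(c(1, NA)), "NA")
})

test_that("mixed-model F equals classical two-way ANOVA on balanced data", {
  set.seed(14)
  d <- tidyr::expand_grid(participant_id = sprintf("P%02d", 1:10),
                          condition_grid()[, c("haptic", "audio")])
  d$y <- 1 + 0.4 * d$haptic + rnorm(nrow(d))
  # remove participant means so the intercept variance estimate is exactly
  # zero and the mixed fit collapses to ordinary least squares
  d$y <- d$y - stats::ave(d$y, d$participant_id) + mean(d$y)
  mixed <- rm_anova(d, "y")
  cls <- stats::anova(stats::lm(
    y ~ haptic * audio,
    data = transform(d, haptic = factor(haptic), audio = factor(audio))
  ))
  expect_equal(mixed$statistic, cls[1:3, "F value"], tolerance = 1e-6)
  expect_equal(mixed$df1, rep(1, 3))
  expect_true(all(mixed$p_value >= 0 & mixed$p_value <= 1))
})

test_that("rm_anova validates its design", {
  d <- tidyr::expand_grid(participant_id = c("P01", "P02"),
                          condition_grid()[, c("haptic", "audio")])
  d$y <- rnorm(8)
  one_level <- d[!d$haptic, ]
  expect_error(rm_anova(one_level, "y"), "haptic")
  expect_error(rm_anova(d[d$participant_id == "P01", ], "y"), "2 participants")
})

test_that("Scheirer-Ray-Hare matches a brute-force SS-on-ranks oracle", {
  # 2x2 with n = 5 per cell, values 1..20: factor haptic separates the low
  # and high ranks perfectly, audio splits within, interaction exactly zero
  d <- tibble::tibble(
    haptic = rep(c(FALSE, TRUE), each = 10),
    audio = rep(rep(c(FALSE, TRUE), each = 5), 2),
    n_collisions = 1:20
  )
  eff <- scheirer_ray_hare(d, "n_collisions")
  # brute force: group mean ranks (no ties, ranks are 1..20)
  r <- 1:20
  ms_total <- sum((r - mean(r))^2) / 19
  ss_h <- 10 * (mean(r[1:10]) - mean(r))^2 + 10 * (mean(r[11:20]) - mean(r))^2
  a_idx <- d$audio
  ss_a <- 10 * (mean(r[!a_idx]) - mean(r))^2 + 10 * (mean(r[a_idx]) - mean(r))^2
  cell_means <- tapply(r, paste(d$haptic, d$audio), mean)
  ss_cells <- 5 * sum((cell_means - mean(r))^2)
  ss_int <- ss_cells - ss_h - ss_a
  expect_equal(eff$statistic, c(ss_h, ss_a, ss_int) / ms_total,
               tolerance = 1e-12)
  expect_equal(eff$statistic[1], 500 / (665 / 19))
})

test_that("Scheirer-Ray-Hare handles complete ties and monotone invariance", {
  d <- tibble::tibble(
    haptic = rep(c(FALSE, TRUE), each = 10),
    audio = rep(rep(c(FALSE, TRUE), each = 5), 2),
    n_collisions = rep(4, 20)
  )
  eff <- scheirer_ray_hare(d, "n_collisions")
  expect_equal(eff$statistic, rep(0, 3))
  expect_equal(eff$p_value, rep(1, 3))

  set.seed(8)
  d$n_collisions <- rpois(20, 3)
  e1 <- scheirer_ray_hare(d, "n_collisions")
  d$n_collisions <- exp(d$n_collisions)  # strictly monotone transform
  e2 <- scheirer_ray_hare(d, "n_collisions")
  expect_equal(e1$statistic, e2$statistic)

  d$haptic <- FALSE
  expect_error(scheirer_ray_hare(d, "n_collisions"), "haptic")
})

test_that("rank-then-ANOVA reproduces the SRH SS decomposition", {
  set.seed(17)
  d <- tidyr::expand_grid(participant_id = sprintf("P%02d", 1:8),
                          condition_grid()[, c("haptic", "audio")])
  d$n_collisions <- rpois(nrow(d), 3)
  eff <- scheirer_ray_hare(d, "n_collisions", tie_correction = FALSE)
  r <- rank(d$n_collisions)
  av <- summary(stats::aov(r ~ haptic * audio,
                           data = transform(d, haptic = factor(haptic),
                                            audio = factor(audio))))[[1]]
  ms_total <- sum((r - mean(r))^2) / (length(r) - 1)
  expect_equal(eff$statistic, av[1:3, "Sum Sq"] / ms_total, tolerance = 1e-10)
})

test_that("condition summaries report mean, SEM and n per cell", {
  d <- make_cells(list(c(2, 4), c(1, 3), c(5), c(2, 2)))
  names(d)[names(d) == "value"] <- "L"
  s <- condition_summaries(d, "L")
  expect_equal(nrow(s), 4)
  none <- s[!s$haptic & !s$audio, ]
  expect_equal(none$mean, 3)
  expect_equal(none$sem, 1)
  single <- s[!s$haptic & s$audio, ]
  expect_true(is.na(single$sem))
  expect_equal(single$n, 1)
  # independent of row order
  s2 <- condition_summaries(d[sample(nrow(d)), ], "L")
  expect_equal(dplyr::arrange(s2, haptic, audio), dplyr::arrange(s, haptic, audio))
})

test_that("removing zero outliers leaves all statistics unchanged", {
  set.seed(23)
  d <- simulate_metrics_cohort(cohort_config(n_participants = 12, seed = 23))
  # bounded uniforms cannot trip the 1.5 IQR fences
  d$completion_time <- runif(nrow(d), 40, 41)
  d$n_collisions <- sample(2:5, nrow(d), replace = TRUE)
  a1 <- analyze_metrics(d, remove_outliers = TRUE)
  a2 <- analyze_metrics(d, remove_outliers = FALSE)
  keep <- a1$outliers$metric[a1$outliers$count == 0]
  expect_true(all(c("completion_time", "n_collisions") %in% keep))
  for (m in keep) {
    expect_equal(a1$effects[a1$effects$metric == m, ],
                 a2$effects[a2$effects$metric == m, ])
  }
})
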