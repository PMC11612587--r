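# Replicate simulation studies over the cohort generator: type-I error
# calibration of the inferential layer and power / direction recovery of the
# programmed condition effects.

#' Programmed-direction checks on a metrics table
#'
#' Evaluates whether the condition-cell means of a cohort realize the
#' programmed effect directions: haptic feedback lowers collision counts and
#' head-pitch entropy while raising completion time and trajectory length;
#' audio feedback raises SPARC; and the haptic trajectory-length increase is
#' smaller with audio on than off (interaction attenuation).
#'
#' @param metrics Metrics tibble.
#' @return Named logical vector, one element per programmed direction.
#' @export
direction_checks <- function(metrics) {
  cm <- function(m, h, a) {
    mean(metrics[[m]][metrics$haptic == h & metrics$audio == a])
  }
  hm <- function(m, h) mean(metrics[[m]][metrics$haptic == h])
  am <- function(m, a) mean(metrics[[m]][metrics$audio == a])
  c(
    collisions_haptic_down = hm("n_collisions", TRUE) < hm("n_collisions", FALSE),
    time_haptic_up = hm("completion_time", TRUE) > hm("completion_time", FALSE),
    L_haptic_up = hm("L", TRUE) > hm("L", FALSE),
    H_pitch_haptic_down = hm("H_pitch", TRUE) < hm("H_pitch", FALSE),
    SPARC_audio_up = am("SPARC", TRUE) > am("SPARC", FALSE),
    L_interaction_attenuated =
      (cm("L", TRUE, TRUE) - cm("L", FALSE, TRUE)) <
      (cm("L", TRUE, FALSE) - cm("L", FALSE, FALSE))
  )
}

#' Type-I error calibration of the repeated-measures mixed ANOVA
#'
#' Simulates metrics-level cohorts with all programmed effects set to zero
#' (participant random intercepts retained) and records, per effect, the
#' fraction of replicates with p below `alpha`. Under a calibrated test the
#' rates sit near `alpha`.
#'
#' @param n_reps Number of replicate cohorts.
#' @param config Base [cohort_config()]; its effects are zeroed internally.
#' @param metric Continuous metric fitted in each replicate.
#' @param alpha Significance level (default 0.05).
#' @param seed RNG seed for the whole study.
#' @return Named numeric vector of rejection rates (haptic, audio,
#'   interaction), with attribute `n_reps`.
#' @export
calibrate_rm_anova <- function(n_reps = 500, config = cohort_config(),
                               metric = "completion_time", alpha = 0.05,
                               seed = 1) {
  config <- null_config(config)
  with_seed(seed, {
    rej <- matrix(FALSE, n_reps, 3,
                  dimnames = list(NULL, c("haptic", "audio", "interaction")))
    for (i in seq_len(n_reps)) {
      d <- simulate_metrics_cohort(config, seed = NULL)
      eff <- rm_anova(d, metric)
      rej[i, ] <- eff$p_value < alpha
    }
    structure(colMeans(rej), n_reps = n_reps)
  })
}

#' Type-I error calibration of the Scheirer-Ray-Hare test
#'
#' Simulates null 2x2 factorial count data (i.i.d. Poisson across all cells,
#' no condition effects) and records per-effect rejection rates at `alpha`.
#'
#' @param n_reps Number of replicates.
#' @param n_participants Participants per replicate (4 observations each).
#' @param lambda Poisson mean of the counts.
#' @param alpha Significance level.
#' @param seed RNG seed.
#' @return Named numeric vector of rejection rates with attribute `n_reps`.
#' @export
calibrate_srh <- function(n_reps = 2000, n_participants = 72, lambda = 3,
                          alpha = 0.05, seed = 1) {
  grid <- condition_grid()
  with_seed(seed, {
    rej <- matrix(FALSE, n_reps, 3,
                  dimnames = list(NULL, c("haptic", "audio", "interaction")))
    template <- tidyr::expand_grid(
      participant_id = sprintf("P%02d", seq_len(n_participants)),
      grid[, c("haptic", "audio")]
    )
    for (i in seq_len(n_reps)) {
      template$n_collisions <- rpois(nrow(template), lambda)
      eff <- scheirer_ray_hare(template, "n_collisions")
      rej[i, ] <- eff$p_value < alpha
    }
    structure(colMeans(rej), n_reps = n_reps)
  })
}

#' Power and direction recovery of the programmed effects
#'
#' Simulates metrics-level cohorts at the configured (non-zero) effect sizes
#' and records, per replicate: rejection of the null for each programmed
#' effect (mixed ANOVA for completion time, L, rank-SPARC, and H_pitch; SRH
#' for collision counts) and agreement of every condition-cell mean ordering
#' with its programmed direction.
#'
#' @param n_reps Number of replicate cohorts (default 100).
#' @param config A [cohort_config()] with the programmed effects.
#' @param alpha Significance level.
#' @param seed RNG seed.
#' @return List: `rejection` (named rates for time_haptic, L_haptic,
#'   L_interaction, SPARC_audio, H_pitch_haptic, collisions_haptic),
#'   `direction` (named rates from [direction_checks()]), `n_reps`.
#' @export
power_study <- function(n_reps = 100, config = cohort_config(), alpha = 0.05,
                        seed = 1) {
  with_seed(seed, {
    rej <- matrix(FALSE, n_reps, 6, dimnames = list(NULL, c(
      "time_haptic", "L_haptic", "L_interaction", "SPARC_audio",
      "H_pitch_haptic", "collisions_haptic"
    )))
    dirs <- NULL
    for (i in seq_len(n_reps)) {
      d <- simulate_metrics_cohort(config, seed = NULL)
      p_time <- rm_anova(d, "completion_time")
      p_L <- rm_anova(d, "L")
      d$SPARC_rank <- rank_transform(d$SPARC)
      p_sparc <- rm_anova(d, "SPARC_rank")
      p_pitch <- rm_anova(d, "H_pitch")
      p_coll <- scheirer_ray_hare(d, "n_collisions")
      pick <- function(eff, which) eff$p_value[eff$effect == which]
      rej[i, ] <- c(
        pick(p_time, "haptic") < alpha,
        pick(p_L, "haptic") < alpha,
        pick(p_L, "interaction") < alpha,
        pick(p_sparc, "audio") < alpha,
        pick(p_pitch, "haptic") < alpha,
        pick(p_coll, "haptic") < alpha
      )
      dc <- direction_checks(d)
      if (is.null(dirs)) {
        dirs <- matrix(FALSE, n_reps, length(dc),
                       dimnames = list(NULL, names(dc)))
      }
      dirs[i, ] <- dc
    }
    list(rejection = colMeans(rej), direction = colMeans(dirs),
         n_reps = n_reps)
  })
}

#' Effect-direction realization over full telemetry cohorts
#'
#' Generates complete telemetry cohorts (walker simulation at the configured
#' sampling rate), extracts the per-trial metrics, and evaluates the
#' programmed-direction checks per cohort; each cohort uses seed
#' `seed + i - 1`.
#'
#' @param n_cohorts Number of cohorts.
#' @param config Base [cohort_config()].
#' @param seed Base seed.
#' @return List: `direction` (per-check agreement rates), `per_cohort`
#'   (logical matrix), `n_cohorts`.
#' @export
effect_direction_study <- function(n_cohorts = 100,
                                   config = cohort_config(), seed = 1) {
  dirs <- NULL
  for (i in seq_len(n_cohorts)) {
    cfg <- config
    cfg$seed <- as.integer(seed + i - 1)
    cohort <- generate_cohort(cfg)
    metrics <- compute_metrics_table(cohort)
    dc <- direction_checks(metrics)
    if (is.null(dirs)) {
      dirs <- matrix(FALSE, n_cohorts, length(dc),
                     dimnames = list(NULL, names(dc)))
    }
    dirs[i, ] <- dc
  }
  list(direction = colMeans(dirs), per_cohort = dirs, n_cohorts = n_cohorts)
}
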