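#' The 2x2 condition grid
#'
#' @return Tibble with logical columns `haptic`, `audio` and a `condition`
#'   label (none, haptic, audio, both), one row per cell.
#' @export
condition_grid <- function() {
  tibble::tibble(
    haptic = c(FALSE, TRUE, FALSE, TRUE),
    audio = c(FALSE, FALSE, TRUE, TRUE),
    condition = c("none", "haptic", "audio", "both")
  )
}

condition_label <- function(haptic, audio) {
  if (haptic && audio) "both" else if (haptic) "haptic" else
    if (audio) "audio" else "none"
}

#' Simulate one obstacle-avoidance trial
#'
#' Steps a 2-D goal-directed walker along the out-and-back course: heading
#' relaxes toward the active waypoint, obstacles within the condition's
#' detection geometry repel it, and Gaussian noise perturbs heading and
#' speed. Condition effects are mechanistic: haptic feedback gives wide
#' body-frame detection at the full range, a higher avoidance gain (wider
#' detours, longer paths), hesitation pauses (longer completion times), and a
#' smaller head-pitch oscillation; audio feedback gives a narrow head-ray
#' detector and lower heading/speed noise (smoother speed profiles); with
#' both, the haptic avoidance gain is attenuated (shorter detours than haptic
#' alone); with neither, only a short "residual vision" range remains.
#' Residual vision persists under every condition -- feedback augments it
#' rather than replacing it. Collisions are flagged per sample while the
#' walker disc overlaps an obstacle disc.
#'
#' @param participant_effects Named list of per-participant multipliers:
#'   `v0_mult`, `pitch_mult`, `hes_mult`, `noise_mult` (all default 1).
#' @param condition Either a condition label ("none", "haptic", "audio",
#'   "both") or a list/row with logical `haptic` and `audio`.
#' @param config A [cohort_config()].
#' @param participant_id Identifier stored on the returned log.
#' @return Trial log tibble (columns t, x, y, z, head_yaw, head_pitch,
#'   head_roll, body_yaw, body_pitch, body_roll, collision) with attributes
#'   `participant_id`, `haptic`, `audio`, and `incomplete` (TRUE when the
#'   walker failed to finish the course within the time cap, in which case a
#'   warning is emitted and downstream metric extraction skips the trial).
#' @export
simulate_trial <- function(participant_effects = list(), condition = "none",
                           config = cohort_config(),
                           participant_id = "P01") {
  pe <- utils::modifyList(
    list(v0_mult = 1, pitch_mult = 1, hes_mult = 1, noise_mult = 1),
    participant_effects
  )
  if (is.character(condition)) {
    grid <- condition_grid()
    row <- grid[grid$condition == condition, ]
    if (nrow(row) != 1) {
      stop("unknown condition '", condition, "'", call. = FALSE)
    }
    haptic <- row$haptic
    audio <- row$audio
  } else {
    haptic <- isTRUE(condition$haptic)
    audio <- isTRUE(condition$audio)
  }
  wk <- config$walker
  cond <- condition_label(haptic, audio)

  if (haptic) {
    detect_range <- config$detection_range
    half_cov <- unname(config$fov_degrees["horizontal"]) / 2
    head_ray <- FALSE
  } else if (audio) {
    detect_range <- config$detection_range
    half_cov <- wk$audio_cone_deg
    head_ray <- TRUE
  } else {
    detect_range <- wk$residual_range
    half_cov <- unname(config$fov_degrees["horizontal"]) / 2
    head_ray <- FALSE
  }

  fs <- config$sampling_rate
  leg <- config$course_length / 2
  waypoints <- matrix(c(0, leg, 0.3, 0), ncol = 2, byrow = TRUE)
  par <- list(
    dt = 1 / fs,
    max_steps = as.integer(wk$max_duration * fs),
    v0 = wk$v0 * pe$v0_mult,
    sigma_speed = unname(if (audio) wk$sigma_speed["audio"] else
      wk$sigma_speed["base"]) * pe$noise_mult,
    tau_speed = wk$tau_speed,
    sigma_heading = unname(if (audio) wk$sigma_heading["audio"] else
      wk$sigma_heading["base"]) * pe$noise_mult,
    k_goal = wk$k_goal,
    avoid_gain = unname(wk$avoid_gain[cond]),
    detect_range = detect_range,
    half_cov_deg = half_cov,
    head_ray = head_ray,
    hesitation_rate = if (haptic) wk$hesitation_rate * pe$hes_mult else 0,
    hesitation_steps = as.integer(round(wk$hesitation_duration * fs)),
    hesitation_factor = wk$hesitation_factor,
    pitch_amp = unname(if (haptic) wk$pitch_amp["haptic"] else
      wk$pitch_amp["base"]) * pe$pitch_mult,
    pitch_freq = wk$pitch_freq,
    sigma_pitch = wk$sigma_pitch,
    scan_amp = wk$scan_amp,
    scan_freq = wk$scan_freq,
    sigma_yaw = wk$sigma_yaw,
    res_range = wk$residual_range,
    res_gain = if (haptic || audio) unname(wk$avoid_gain["none"]) else 0,
    res_half_cov = unname(config$fov_degrees["horizontal"]) / 2,
    pitch_phase = runif(1, 0, 2 * pi),
    scan_phase = runif(1, 0, 2 * pi),
    walker_radius = wk$walker_radius,
    waypoint_tol = wk$waypoint_tol
  )
  res <- walker_trial_cpp(
    as.matrix(config$obstacle_layout[, c("x", "y", "radius")]),
    waypoints, par
  )
  m <- res$samples
  colnames(m) <- c("t", "x", "y", "z", "head_yaw", "head_pitch", "head_roll",
                   "body_yaw", "body_pitch", "body_roll", "collision")
  trial <- tibble::as_tibble(m)
  trial$collision <- trial$collision > 0
  attr(trial, "participant_id") <- participant_id
  attr(trial, "haptic") <- haptic
  attr(trial, "audio") <- audio
  attr(trial, "incomplete") <- isTRUE(res$incomplete)
  if (isTRUE(res$incomplete)) {
    warning("trial ", participant_id, "/", cond,
            " did not reach the goal within the time cap; flagged incomplete",
            call. = FALSE)
  }
  trial
}

#' Generate a full synthetic cohort
#'
#' Produces 4 trial logs per participant (one per haptic x audio cell, in a
#' per-participant random order drawn uniformly from the 24 possible
#' orderings), a manifest, and a questionnaire table. Between-participant
#' heterogeneity enters through lognormal multipliers on preferred speed,
#' head-pitch amplitude, hesitation propensity, and movement noise. The
#' generator is fully seeded: identical (config, seed) pairs regenerate
#' byte-identical cohorts.
#'
#' @param config A [cohort_config()].
#' @return List with elements `trials` (named list of trial logs, names
#'   `<participant>_<condition>`), `manifest` (tibble: participant_id,
#'   haptic, audio, order_index, log_path), `questionnaire` (tibble, one row
#'   per participant), and the `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  grid <- condition_grid()
  with_seed(config$seed, {
    trials <- list()
    manifest <- vector("list", config$n_participants * 4)
    wk <- config$walker
    for (p in seq_len(config$n_participants)) {
      pid <- sprintf("P%02d", p)
      pe <- list(
        v0_mult = exp(rnorm(1, 0, wk$v0_participant_cv)),
        pitch_mult = exp(rnorm(1, 0, wk$pitch_participant_cv)),
        hes_mult = exp(rnorm(1, 0, 0.3)),
        noise_mult = exp(rnorm(1, 0, 0.15))
      )
      order <- sample.int(4)
      for (k in seq_len(4)) {
        cell <- grid[order[k], ]
        trial <- simulate_trial(pe, cell, config, participant_id = pid)
        key <- paste0(pid, "_", cell$condition)
        trials[[key]] <- trial
        manifest[[(p - 1) * 4 + k]] <- tibble::tibble(
          participant_id = pid,
          haptic = cell$haptic,
          audio = cell$audio,
          order_index = k,
          log_path = file.path("trials", paste0(key, ".csv"))
        )
      }
    }
    questionnaire <- generate_questionnaire(
      config$n_participants, config$questionnaire_probs
    )
    list(
      trials = trials,
      manifest = dplyr::bind_rows(manifest),
      questionnaire = questionnaire,
      config = config
    )
  })
}

#' Sample synthetic questionnaire answers
#'
#' Closed items are drawn from the configured categorical probabilities;
#' free-text items q5 and q7 receive a fixed placeholder.
#'
#' @param n Number of participants.
#' @param probs Named list of per-item category probabilities; see
#'   [default_questionnaire_probs()].
#' @return Tibble with one row per participant, columns participant_id and
#'   q1..q8.
#' @export
generate_questionnaire <- function(n, probs = default_questionnaire_probs()) {
  draw <- function(p) {
    sample(names(p), n, replace = TRUE, prob = p)
  }
  tibble::tibble(
    participant_id = sprintf("P%02d", seq_len(n)),
    q1_vr_experience = draw(probs$q1_vr_experience),
    q2_engaged = draw(probs$q2_engaged),
    q3_motion_sickness = draw(probs$q3_motion_sickness),
    q4_best_performance_condition = draw(probs$q4_best_performance_condition),
    q5_performance_reason = "(free text)",
    q6_preferred_condition = draw(probs$q6_preferred_condition),
    q7_preference_reason = "(free text)",
    q8_interest = draw(probs$q8_interest)
  )
}

#' Generate a metrics-level synthetic cohort
#'
#' Draws per-trial metric values directly from the stochastic model that the
#' inferential layer assumes: for each continuous metric, value = baseline
#' mean + sd_within * (participant intercept + programmed shifts + noise),
#' with the programmed haptic, audio, and interaction shifts in within-SD
#' units; collision counts are Poisson with a log-rate that carries the
#' participant intercept and the programmed shifts. Used for replicate
#' simulation studies (type-I calibration, power/recovery) where full
#' telemetry is unnecessary.
#'
#' @param config A [cohort_config()]; its `effect_sizes`, `participant_sd`,
#'   and `metric_baselines` drive the draw.
#' @param seed Optional seed; defaults to `config$seed`. Use `NULL` to draw
#'   from the current RNG stream.
#' @return Metrics tibble: participant_id, haptic, audio, one column per
#'   metric.
#' @export
simulate_metrics_cohort <- function(config = cohort_config(),
                                    seed = config$seed) {
  gen <- function() {
    n <- config$n_participants
    grid <- condition_grid()
    df <- tidyr::expand_grid(
      participant_id = sprintf("P%02d", seq_len(n)),
      grid[, c("haptic", "audio")]
    )
    h <- as.numeric(df$haptic)
    a <- as.numeric(df$audio)
    for (m in METRIC_NAMES) {
      es <- config$effect_sizes[[m]]
      shift <- es["haptic"] * h + es["audio"] * a + es["interaction"] * h * a
      b <- rnorm(n, 0, config$participant_sd[[m]])[match(
        df$participant_id, sprintf("P%02d", seq_len(n))
      )]
      base <- config$metric_baselines[[m]]
      if (m == "n_collisions") {
        lambda <- unname(base["lambda"]) * exp(b + shift)
        df[[m]] <- rpois(nrow(df), lambda)
      } else {
        df[[m]] <- unname(base["mean"]) +
          unname(base["sd"]) * (b + shift + rnorm(nrow(df)))
      }
    }
    df
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}
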