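#' @keywords internal
"_PACKAGE"

#' @useDynLib navkin, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @importFrom stats rnorm runif rpois quantile pchisq sd
NULL

# metrics produced per trial; collision counts are the one discrete metric
METRIC_NAMES <- c("completion_time", "L", "SPARC", "H_pitch", "H_chi",
                  "n_collisions")
EFFECT_NAMES <- c("haptic", "audio", "interaction")

#' Default obstacle layout for the out-and-back corridor
#'
#' Obstacles staggered left and right of the corridor midline so that a
#' straight walk would clip them; encountered on both legs.
#'
#' @param course_length Total out-and-back course length in meters.
#' @return Tibble with columns x, y, radius (meters).
#' @export
default_obstacles <- function(course_length = 40) {
  leg <- course_length / 2
  y <- seq(0.15 * leg, 0.925 * leg, length.out = 8)
  tibble::tibble(
    x = rep(c(-0.35, 0.35), length.out = 8),
    y = y,
    radius = 0.35
  )
}

#' Default programmed condition effects, in within-subject SD units
#'
#' Standardized shifts applied by the metric-level cohort generator: haptic
#' feedback raises completion time and trajectory length, lowers collision
#' counts (log-rate shift) and head-pitch entropy; audio feedback raises
#' SPARC smoothness; the haptic x audio interaction attenuates the haptic
#' trajectory-length increase.
#'
#' @return Named list (one element per metric) of named numeric vectors with
#'   entries haptic, audio, interaction.
#' @export
default_effect_sizes <- function() {
  list(
    completion_time = c(haptic = 0.6,  audio = 0,   interaction = 0),
    L               = c(haptic = 0.8,  audio = 0,   interaction = -0.7),
    SPARC           = c(haptic = 0,    audio = 0.6, interaction = 0),
    H_pitch         = c(haptic = -0.6, audio = 0,   interaction = 0),
    H_chi           = c(haptic = 0,    audio = 0,   interaction = 0),
    n_collisions    = c(haptic = -0.5, audio = 0,   interaction = 0)
  )
}

#' Default between-participant random-intercept scales
#'
#' In within-subject SD units for the continuous metrics; on the log rate for
#' collision counts.
#'
#' @return Named numeric vector, one element per metric.
#' @export
default_participant_sd <- function() {
  c(completion_time = 0.8, L = 0.8, SPARC = 0.8, H_pitch = 0.8,
    H_chi = 0.8, n_collisions = 0.3)
}

# metric-level generator baselines: mean and within-subject sd on the
# natural scale (collisions: baseline Poisson rate per trial)
default_metric_baselines <- function() {
  list(
    completion_time = c(mean = 45, sd = 6),
    L               = c(mean = 44, sd = 3),
    SPARC           = c(mean = -7, sd = 1),
    H_pitch         = c(mean = 4.0, sd = 0.5),
    H_chi           = c(mean = 4.5, sd = 0.5),
    n_collisions    = c(lambda = 3, sd = NA)
  )
}

#' Default mechanism parameters for the telemetry walker
#'
#' Units: speeds m/s, rates 1/s, angles degrees, angular noise deg/sqrt(s).
#' Condition-dependent entries are given as off/on pairs resolved by
#' [simulate_trial()].
#'
#' @return Named list of walker parameters.
#' @export
default_walker_params <- function() {
  list(
    v0 = 1.0,                    # preferred walking speed
    v0_participant_cv = 0.08,    # lognormal between-participant speed scale
    sigma_speed = c(base = 0.16, audio = 0.085),  # relative speed noise
    tau_speed = 0.4,             # AR(1) time constant of speed noise, s
    sigma_heading = c(base = 22, audio = 10),     # heading noise, deg/sqrt(s)
    k_goal = 2.5,                # goal-attraction rate, 1/s
    avoid_gain = c(none = 110, haptic = 140, audio = 110, both = 95),
    residual_range = 1.1,        # detection range without feedback, m
    audio_cone_deg = 15,         # half-width of the head-ray detection cone
    hesitation_rate = 0.35,      # haptic hesitation hazard while detecting, 1/s
    hesitation_duration = 0.5,   # s
    hesitation_factor = 0.15,    # speed multiplier during a hesitation
    pitch_amp = c(base = 8, haptic = 5.5),  # head-pitch oscillation amp, deg
    pitch_freq = 0.35,           # Hz
    sigma_pitch = 1.2,           # deg
    pitch_participant_cv = 0.15,
    scan_amp = 30,               # head-yaw scanning amplitude, deg
    scan_freq = 0.25,            # Hz
    sigma_yaw = 1.5,             # deg
    walker_radius = 0.25,        # m
    waypoint_tol = 0.6,          # m
    max_duration = 120           # hard time cap, s
  )
}

# default questionnaire answer probabilities (category proportions of the
# closed items; free-text q5/q7 get a fixed placeholder)
default_questionnaire_probs <- function() {
  list(
    q1_vr_experience = c(yes = 45, no = 27) / 72,
    q2_engaged = c(yes = 55, no = 17) / 72,
    q3_motion_sickness = c(yes = 4, no = 68) / 72,
    q4_best_performance_condition =
      c(none = 5, haptic = 10, audio = 17, both = 36, unsure = 4) / 72,
    q6_preferred_condition =
      c(none = 4, haptic = 13, audio = 23, both = 29, unsure = 3) / 72,
    q8_interest = c(not_at_all = 0, slightly = 0, moderately = 2,
                    fairly = 28, extremely = 42) / 72
  )
}

#' Cohort generator configuration
#'
#' Bundles and validates every parameter of the synthetic cohort: design size,
#' sampling, course geometry, condition-dependent detection, programmed effect
#' sizes, between-participant heterogeneity, and the RNG seed. Identical
#' (config, seed) pairs regenerate byte-identical cohorts.
#'
#' @param n_participants Number of participants (>= 2; default 72). Every
#'   participant performs all 4 condition cells of the 2x2 haptic x audio
#'   grid, in a randomized order.
#' @param sampling_rate Telemetry sampling rate in Hz (default 72).
#' @param course_length Total out-and-back course length in meters (default
#'   40: 20 m out, 20 m back).
#' @param obstacle_layout Tibble of obstacle centers and radii (x, y, radius).
#' @param detection_range Feedback detection range in meters (default 2.5).
#' @param fov_sectors Number of haptic belt sectors (default 10).
#' @param fov_degrees Named vector, horizontal and vertical field-of-view
#'   spans in degrees (default 89 and 93).
#' @param effect_sizes Programmed standardized shifts per metric; see
#'   [default_effect_sizes()]. Partial lists are merged over the defaults;
#'   unknown metric or effect names are an error.
#' @param participant_sd Between-participant random-intercept scale per
#'   metric; see [default_participant_sd()].
#' @param metric_baselines Metric-level generator baselines (means and
#'   within-subject SDs).
#' @param walker Walker mechanism parameters; see [default_walker_params()].
#' @param questionnaire_probs Categorical answer probabilities per item.
#' @param seed RNG seed (integer).
#' @return Object of class `cohort_config` (a named list).
#' @export
cohort_config <- function(n_participants = 72,
                          sampling_rate = 72,
                          course_length = 40,
                          obstacle_layout = default_obstacles(course_length),
                          detection_range = 2.5,
                          fov_sectors = 10,
                          fov_degrees = c(horizontal = 89, vertical = 93),
                          effect_sizes = list(),
                          participant_sd = default_participant_sd(),
                          metric_baselines = default_metric_baselines(),
                          walker = default_walker_params(),
                          questionnaire_probs = default_questionnaire_probs(),
                          seed = 1L) {
  if (!is.numeric(n_participants) || n_participants < 2) {
    stop("`n_participants` must be at least 2", call. = FALSE)
  }
  if (sampling_rate <= 0) stop("`sampling_rate` must be positive", call. = FALSE)
  if (detection_range <= 0) stop("`detection_range` must be positive", call. = FALSE)
  effect_sizes <- merge_effect_sizes(default_effect_sizes(), effect_sizes)
  bad <- setdiff(names(participant_sd), METRIC_NAMES)
  if (length(bad)) {
    stop("unknown participant_sd metric: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      sampling_rate = sampling_rate,
      course_length = course_length,
      obstacle_layout = tibble::as_tibble(obstacle_layout),
      detection_range = detection_range,
      fov_sectors = as.integer(fov_sectors),
      fov_degrees = fov_degrees,
      effect_sizes = effect_sizes,
      participant_sd = participant_sd,
      metric_baselines = metric_baselines,
      walker = walker,
      questionnaire_probs = questionnaire_probs,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

merge_effect_sizes <- function(defaults, user) {
  if (length(user) == 0) return(defaults)
  bad <- setdiff(names(user), METRIC_NAMES)
  if (length(bad)) {
    stop("unknown effect-size metric: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (m in names(user)) {
    v <- user[[m]]
    bad_eff <- setdiff(names(v), EFFECT_NAMES)
    if (is.null(names(v)) || length(bad_eff)) {
      stop("effect sizes for '", m, "' must be named with: ",
           paste(EFFECT_NAMES, collapse = ", "),
           if (length(bad_eff)) paste0(" (got: ",
                                       paste(bad_eff, collapse = ", "), ")"),
           call. = FALSE)
    }
    defaults[[m]][names(v)] <- v
  }
  defaults
}

#' Zero out all programmed condition effects (null configuration)
#'
#' @param config A [cohort_config()].
#' @return The same configuration with every effect size set to 0; used for
#'   type-I error calibration.
#' @export
null_config <- function(config = cohort_config()) {
  config$effect_sizes <- lapply(config$effect_sizes, function(v) {
    v[] <- 0
    v
  })
  config
}

# Run code with a locally set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
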