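#' Trajectory length of a 2-D path
#'
#' Sum of Euclidean distances between consecutive 2-D body positions,
#' L = sum over t of ||p[t+1] - p[t]||. Translation- and rotation-invariant
#' and additive over concatenated segments.
#'
#' @param positions Two-column numeric matrix (or data frame) of x, y in
#'   meters, one row per frame; at least 2 rows.
#' @return Trajectory length in meters (>= 0).
#' @export
trajectory_length <- function(positions) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 2) stop("need at least 2 position samples", call. = FALSE)
  d <- diff(positions[, 1:2, drop = FALSE])
  sum(sqrt(rowSums(d^2)))
}

#' Spectral arc length (SPARC) movement-smoothness index
#'
#' Arc length (negated) of the normalized magnitude spectrum of a speed
#' profile, up to an adaptive cutoff frequency. The spectrum is computed by
#' FFT with zero-padding to `zero_pad_factor` times the series length
#' (rounded up to a power of two), normalized by its maximum over the grid
#' below `f_max`. The cutoff f_c is the largest grid frequency below `f_max`
#' whose normalized magnitude exceeds `v_threshold`; the index is
#'
#'   SPARC = - sum_i sqrt( ((f[i+1]-f[i]) / f_c)^2 + (V[i+1]-V[i])^2 )
#'
#' over the components up to f_c. Smoother movement (less high-frequency
#' content in the speed) gives a higher (less negative) value. The index is
#' invariant to uniform speed scaling and to time reversal.
#'
#' @param v Speed profile (m/s), at least 8 samples, not all zero.
#' @param sampling_rate Sampling rate in Hz; must exceed `2 * f_max`.
#' @param v_threshold Normalized magnitude threshold V-bar (default 0.05).
#' @param f_max Frequency ceiling in Hz (default 10).
#' @param zero_pad_factor Zero-padding multiple before the FFT (default 4).
#' @return SPARC, dimensionless and <= 0.
#' @export
sparc <- function(v, sampling_rate, v_threshold = 0.05, f_max = 10,
                  zero_pad_factor = 4) {
  if (length(v) < 8) stop("speed series must have at least 8 samples", call. = FALSE)
  if (!(v_threshold > 0 && v_threshold < 1)) {
    stop("`v_threshold` must lie in (0, 1)", call. = FALSE)
  }
  if (f_max <= 0) stop("`f_max` must be positive", call. = FALSE)
  if (sampling_rate <= 2 * f_max) {
    stop("`sampling_rate` must exceed 2 * f_max", call. = FALSE)
  }
  n <- length(v)
  nfft <- 2^ceiling(log2(n * max(1L, zero_pad_factor)))
  spec <- abs(stats::fft(c(v, rep(0, nfft - n))))
  freq <- (seq_len(nfft) - 1) * sampling_rate / nfft
  sel <- freq < f_max
  vmax <- max(spec[sel])
  if (vmax == 0) stop("all-zero speed profile: spectrum undefined", call. = FALSE)
  vn <- spec[sel] / vmax
  above <- which(vn > v_threshold)
  if (length(above) == 0) {
    stop("no frequency component exceeds the threshold: degenerate cutoff",
         call. = FALSE)
  }
  n_fc <- max(above)
  f_c <- freq[sel][n_fc]
  if (n_fc < 2 || f_c <= 0) return(0)
  fs <- freq[sel][seq_len(n_fc)]
  vs <- vn[seq_len(n_fc)]
  -sum(sqrt((diff(fs) / f_c)^2 + diff(vs)^2))
}

#' Shannon entropy of an angle series over 1-degree bins
#'
#' Bins of width `bin_width` degrees anchored at integer multiples of the
#' width (..., [-1, 0), [0, 1), ...); p is the relative frequency per
#' occupied bin and H = -sum p log2 p, in bits. Empty bins contribute
#' nothing; H is bounded above by log2(number of occupied bins) and is
#' invariant to shifting all samples by full turns after wrapping.
#'
#' @param angles Numeric vector of angles in degrees, finite, length >= 1.
#' @param bin_width Bin width in degrees (default 1).
#' @return Entropy in bits (>= 0).
#' @export
shannon_entropy <- function(angles, bin_width = 1) {
  if (length(angles) == 0) stop("empty angle series", call. = FALSE)
  if (!all(is.finite(angles))) stop("angles must be finite", call. = FALSE)
  if (bin_width <= 0) stop("`bin_width` must be positive", call. = FALSE)
  counts <- table(floor(angles / bin_width))
  p <- as.numeric(counts) / length(angles)
  -sum(p * log2(p))
}

#' Collision count of a trial
#'
#' Number of rising edges of the per-sample collision flag: one count per
#' continuous overlap episode with an obstacle.
#'
#' @param trial A trial log (see [read_trial_log()]) or a logical/0-1 vector
#'   of per-sample collision flags.
#' @return Non-negative integer count.
#' @export
collision_count <- function(trial) {
  flags <- if (is.data.frame(trial)) trial$collision else trial
  flags <- as.integer(as.logical(flags))
  sum(diff(c(0L, flags)) == 1L)
}

#' Completion time of a trial
#'
#' @param trial A trial log with a `t` column (seconds) or a numeric time
#'   vector.
#' @return Elapsed time `t_last - t_first` in seconds.
#' @export
completion_time <- function(trial) {
  t <- if (is.data.frame(trial)) trial$t else trial
  if (length(t) < 1) stop("empty trial", call. = FALSE)
  t[length(t)] - t[1]
}

#' Per-trial metrics from a telemetry log
#'
#' Applies quadratic smoothing to the body position and the angle series
#' (yaw angles are unwrapped across the +/-180 seam first), then computes the
#' six per-trial metrics: completion time (s), collision count, trajectory
#' length L (m), SPARC smoothness of the 2-D speed profile, and Shannon
#' entropies H(theta_h) of the smoothed head pitch and H(chi) of the smoothed
#' head-body yaw difference, both over 1-degree bins.
#'
#' @param trial A trial log as returned by [read_trial_log()] or
#'   [simulate_trial()].
#' @param sampling_rate Sampling rate of the log in Hz.
#' @param smoothing_window Nominal smoothing window in samples (default 20).
#' @param sparc_params List with elements `v_threshold`, `f_max`,
#'   `zero_pad_factor`; see [sparc()].
#' @param entropy_bin Entropy bin width in degrees (default 1).
#' @return One-row tibble: participant_id, haptic, audio, completion_time,
#'   n_collisions, L, SPARC, H_pitch, H_chi, plus the provenance columns
#'   smoothing_window, sparc_v_threshold, sparc_f_max.
#' @export
compute_metrics <- function(trial, sampling_rate,
                            smoothing_window = 20,
                            sparc_params = list(v_threshold = 0.05,
                                                f_max = 10,
                                                zero_pad_factor = 4),
                            entropy_bin = 1) {
  stopifnot(is.data.frame(trial), nrow(trial) >= 3)
  dt <- 1 / sampling_rate
  xs <- smooth_series(trial$x, smoothing_window)
  ys <- smooth_series(trial$y, smoothing_window)
  pitch_s <- smooth_series(trial$head_pitch, smoothing_window)
  hyaw_s <- smooth_angle_series(trial$head_yaw, smoothing_window)
  byaw_s <- smooth_angle_series(trial$body_yaw, smoothing_window)
  pos <- cbind(xs, ys)
  v <- speed_profile(pos, dt)
  tibble::tibble(
    participant_id = attr_or(trial, "participant_id", NA_character_),
    haptic = attr_or(trial, "haptic", NA),
    audio = attr_or(trial, "audio", NA),
    completion_time = completion_time(trial),
    n_collisions = collision_count(trial),
    L = trajectory_length(pos),
    SPARC = sparc(v, sampling_rate,
                  v_threshold = sparc_params$v_threshold,
                  f_max = sparc_params$f_max,
                  zero_pad_factor = sparc_params$zero_pad_factor),
    H_pitch = shannon_entropy(pitch_s, entropy_bin),
    H_chi = shannon_entropy(yaw_difference(hyaw_s, byaw_s), entropy_bin),
    smoothing_window = smoothing_window,
    sparc_v_threshold = sparc_params$v_threshold,
    sparc_f_max = sparc_params$f_max
  )
}

attr_or <- function(x, which, default) {
  a <- attr(x, which, exact = TRUE)
  if (is.null(a)) default else a
}

#' Metrics table for a whole cohort
#'
#' @param cohort A cohort as returned by [generate_cohort()], or a named list
#'   of trial logs.
#' @param sampling_rate Sampling rate in Hz; defaults to the cohort's.
#' @param ... Passed to [compute_metrics()].
#' @return Tibble with one row per trial. Trials flagged incomplete by the
#'   simulator are dropped with a warning.
#' @export
compute_metrics_table <- function(cohort, sampling_rate = NULL, ...) {
  trials <- if (!is.null(cohort$trials)) cohort$trials else cohort
  if (is.null(sampling_rate)) sampling_rate <- cohort$config$sampling_rate
  stopifnot(!is.null(sampling_rate))
  incomplete <- vapply(trials, function(tr) isTRUE(attr(tr, "incomplete")),
                       logical(1))
  if (any(incomplete)) {
    warning(sum(incomplete), " incomplete trial(s) excluded from metrics: ",
            paste(names(trials)[incomplete], collapse = ", "), call. = FALSE)
    trials <- trials[!incomplete]
  }
  dplyr::bind_rows(lapply(trials, compute_metrics,
                          sampling_rate = sampling_rate, ...))
}
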