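# Independent brute-force oracles and small fixture builders used across the
# suite. The oracles deliberately avoid the package's code paths.

# SPARC by direct DFT summation (no FFT), same spectral definition
sparc_brute <- function(v, fs, vthr = 0.05, fmax = 10, pad = 4) {
  n <- length(v)
  nfft <- 2^ceiling(log2(n * pad))
  freq <- (0:(nfft - 1)) * fs / nfft
  sel <- which(freq < fmax)
  V <- vapply(sel - 1, function(k) {
    Mod(sum(v * exp(-2i * pi * k * (0:(n - 1)) / nfft)))
  }, numeric(1))
  vn <- V / max(V)
  nfc <- max(which(vn > vthr))
  fc <- freq[sel][nfc]
  if (nfc < 2 || fc <= 0) return(0)
  f <- freq[sel][1:nfc]
  -sum(sqrt((diff(f) / fc)^2 + diff(vn[1:nfc])^2))
}

# minimum-jerk speed profile (bell curve), duration secs at fs Hz
min_jerk_speed <- function(duration = 2, fs = 50, peak = 1.5) {
  tau <- seq(0, 1, length.out = round(duration * fs))
  peak * (30 * tau^2 - 60 * tau^3 + 30 * tau^4) / 1.875
}

# band-limited additive noise (random sinusoids between f_lo and f_hi)
band_noise <- function(n, fs, amp = 0.15, f_lo = 2, f_hi = 9, k = 4) {
  t <- (0:(n - 1)) / fs
  f <- runif(k, f_lo, f_hi)
  ph <- runif(k, 0, 2 * pi)
  a <- runif(k, 0.3, 1) * amp
  colSums(a * sin(outer(2 * pi * f, t) + ph))
}

# a small, fast generator configuration for telemetry tests
fast_config <- function(n = 4, seed = 1, ...) {
  cohort_config(
    n_participants = n,
    course_length = 16,
    obstacle_layout = default_obstacles(16)[c(1, 3, 5, 7), ],
    seed = seed,
    ...
  )
}

# hand-built 10-sample straight-walk trial log with locked yaws
hand_trial <- function() {
  t <- seq(0, 0.18, by = 0.02)   # 50 Hz, 10 samples
  tibble::tibble(
    t = t, x = t * 1.0, y = 0, z = 1.6,
    head_yaw = 90, head_pitch = 5.3, head_roll = 0,
    body_yaw = 90, body_pitch = 0, body_roll = 0,
    collision = c(FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE,
                  FALSE, FALSE)
  )
}
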