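#' Wrap angles to the half-open interval (-180, 180] degrees
#'
#' @param x Numeric vector of angles in degrees.
#' @return Numeric vector of the same length, wrapped to (-180, 180].
#' @examples
#' wrap_angle(c(190, -190, 180, -180, 360))
#' @export
wrap_angle <- function(x) {
  w <- x - 360 * floor((x + 180) / 360) # [-180, 180)
  w[!is.na(w) & w == -180] <- 180       # convention: (-180, 180]
  w
}

#' Unwrap a degree angle series onto a continuous branch
#'
#' Removes jumps across the +/-180 degree seam so that regression smoothing of
#' yaw angles is meaningful; successive differences are assumed below 180
#' degrees in magnitude (guaranteed at headset sampling rates).
#'
#' @param x Numeric vector of angles in degrees.
#' @return Numeric vector on a continuous branch, same length; `wrap_angle()`
#'   of the result reproduces `wrap_angle(x)`.
#' @export
unwrap_angle <- function(x) {
  if (length(x) < 2) return(x)
  x[1] + c(0, cumsum(wrap_angle(diff(x))))
}

# Centered quadratic least-squares weights for a symmetric window of
# half-width h: fitted value at the window center as a linear filter.
sg_weights <- function(h) {
  j <- -h:h
  X <- cbind(1, j, j^2)
  drop((solve(crossprod(X)) %*% t(X))[1, ])
}

#' Quadratic local-regression smoothing of a uniformly sampled series
#'
#' Each output sample is the value at the center of a local least-squares
#' quadratic fit over a symmetric window. An even `window` is realized as the
#' nearest odd point count (e.g. the default 20 becomes 21 points, 10 on each
#' side), because only centered fits are unbiased at interior points. Near the
#' series ends the window is truncated symmetrically; the first and last
#' samples, where no symmetric neighborhood exists, are returned unchanged
#' (a quadratic through fewer than 4 points interpolates them exactly).
#'
#' The operator is linear in the input and reproduces polynomials of degree
#' at most 2 exactly.
#'
#' @param values Numeric vector, uniformly sampled, length >= 3.
#' @param window Nominal window size in samples (default 20).
#' @param order Polynomial degree; only 2 is supported.
#' @return Numeric vector of the same length as `values`.
#' @export
smooth_series <- function(values, window = 20, order = 2) {
  if (order != 2) {
    stop("only quadratic (order = 2) smoothing is supported", call. = FALSE)
  }
  if (window < order + 1) {
    stop("`window` must be at least order + 1 = 3", call. = FALSE)
  }
  if (!is.numeric(values)) stop("`values` must be numeric", call. = FALSE)
  n <- length(values)
  if (n < 3) stop("series must have at least 3 samples", call. = FALSE)
  h <- max(1L, as.integer(floor(window / 2)))
  h <- min(h, as.integer(floor((n - 1) / 2)))
  out <- as.numeric(stats::filter(values, sg_weights(h), sides = 2))
  for (i in which(is.na(out))) {
    hi <- min(i - 1L, n - i)
    out[i] <- if (hi < 1L) values[i] else
      sum(sg_weights(hi) * values[(i - hi):(i + hi)])
  }
  out
}

# Smooth a yaw-like angle series: unwrap to a continuous branch, smooth,
# re-wrap. Pitch/roll stay within (-90, 90) and are smoothed directly.
smooth_angle_series <- function(values, window = 20) {
  wrap_angle(smooth_series(unwrap_angle(values), window = window))
}

#' Speed profile from a 2-D position series
#'
#' @param positions Two-column numeric matrix (or data frame) of x, y body
#'   positions in meters, one row per frame.
#' @param dt Sampling interval in seconds (> 0).
#' @return Numeric vector of length `nrow(positions) - 1`;
#'   `v[t] = ||p[t+1] - p[t]|| / dt`, non-negative.
#' @export
speed_profile <- function(positions, dt) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 2) stop("need at least 2 position samples", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) {
    stop("`dt` must be a positive scalar", call. = FALSE)
  }
  d <- diff(positions[, 1:2, drop = FALSE])
  sqrt(rowSums(d^2)) / dt
}

#' Head-body yaw difference series
#'
#' Per-sample difference chi = head yaw - body yaw, wrapped to (-180, 180]
#' degrees; a measure of head scanning relative to the trunk.
#'
#' @param head_yaw,body_yaw Numeric vectors of equal length, degrees.
#' @return Numeric vector chi in degrees, wrapped to (-180, 180].
#' @export
yaw_difference <- function(head_yaw, body_yaw) {
  if (length(head_yaw) != length(body_yaw)) {
    stop("head and body yaw series must have equal length", call. = FALSE)
  }
  wrap_angle(head_yaw - body_yaw)
}
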