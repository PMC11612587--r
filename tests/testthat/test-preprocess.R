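test_that("angle wrapping maps to (-180, 180] and handles the seam", {
  expect_equal(wrap_angle(c(190, -190, 180, -180, 360, 0)),
               c(-170, 170, 180, 180, 0, 0))
  expect_equal(yaw_difference(179, -179), -2)
  expect_equal(yaw_difference(rep(30, 5) + 40, rep(40, 5)), rep(30, 5))
  expect_equal(yaw_difference(c(10, 20), c(10, 20)), c(0, 0))
  expect_error(yaw_difference(1:3, 1:2), "equal length")
})

test_that("unwrapping removes seam jumps and is inverted by wrapping", {
  x <- wrap_angle(cumsum(c(170, 30, 30, 30, 30)))
  u <- unwrap_angle(x)
  expect_equal(diff(u), rep(30, 4))
  expect_equal(wrap_angle(u), x)
})

test_that("quadratic smoothing reproduces polynomials of degree <= 2", {
  t <- seq(0, 5, length.out = 100)
  for (y in list(rep(3.7, 100), 2 - 0.5 * t, 1 + 2 * t - 0.3 * t^2)) {
    expect_equal(smooth_series(y, 20), y, tolerance = 1e-9)
  }
})

test_that("smoothing is linear and length preserving", {
  set.seed(1)
  x <- rnorm(200)
  y <- rnorm(200)
  expect_length(smooth_series(x, 20), 200)
  expect_equal(smooth_series(2 * x + 3 * y, 20),
               2 * smooth_series(x, 20) + 3 * smooth_series(y, 20))
})

test_that("smoothing reduces noise around a quadratic trend", {
  t <- seq(0, 10, length.out = 1000)
  truth <- 1 + 0.8 * t - 0.05 * t^2
  set.seed(42)
  worse <- 0L
  for (i in 1:50) {
    noisy <- truth + rnorm(1000, sd = 0.3)
    sm <- smooth_series(noisy, 20)
    if (sqrt(mean((sm - truth)^2)) >= sqrt(mean((noisy - truth)^2))) {
      worse <- worse + 1L
    }
  }
  expect_equal(worse, 0L)
})

test_that("smoothing rejects degenerate inputs", {
  expect_error(smooth_series(c(1, 2), 20), "at least 3")
  expect_error(smooth_series(1:10, 2), "at least")
  expect_error(smooth_series(1:10, 20, order = 3), "order = 2")
})

test_that("speed profile matches closed forms", {
  # straight 1 m/s walk sampled at 10 Hz
  p <- cbind(seq(0, 2, by = 0.1), 0)
  expect_equal(speed_profile(p, 0.1), rep(1, 20))
  # stationary walker
  expect_equal(speed_profile(cbind(rep(1, 9), rep(2, 9)), 0.1), rep(0, 8))
  # circular path: constant speed r*omega within O(dt) discretization
  r <- 2; omega <- 0.5; dt <- 0.001
  th <- seq(0, 2 * pi, by = omega * dt)
  v <- speed_profile(cbind(r * cos(th), r * sin(th)), dt)
  expect_equal(v, rep(r * omega, length(v)), tolerance = 1e-4)
  expect_error(speed_profile(p, 0), "positive")
  expect_error(speed_profile(p[1, , drop = FALSE], 0.1), "at least 2")
})
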