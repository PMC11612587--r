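test_that("trajectory length is exact on simple figures", {
  # 11 collinear points spaced 0.5 m
  expect_equal(trajectory_length(cbind(seq(0, 5, by = 0.5), 0)), 5)
  # closed unit square traversed corner to corner
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  expect_equal(trajectory_length(sq), 4)
  expect_error(trajectory_length(sq[1, , drop = FALSE]), "at least 2")
})

test_that("trajectory length matches brute-force pairwise summation", {
  set.seed(7)
  p <- apply(matrix(rnorm(2000, sd = 0.1), ncol = 2), 2, cumsum)
  brute <- 0
  for (i in 1:(nrow(p) - 1)) {
    brute <- brute + sqrt(sum((p[i + 1, ] - p[i, ])^2))
  }
  expect_equal(trajectory_length(p), brute, tolerance = 1e-12)
})

test_that("trajectory length is rigid-motion invariant and additive", {
  set.seed(8)
  p <- apply(matrix(rnorm(200, sd = 0.2), ncol = 2), 2, cumsum)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(trajectory_length(p %*% rot), trajectory_length(p))
  expect_equal(trajectory_length(sweep(p, 2, c(5, -3), "+")),
               trajectory_length(p))
  k <- 40
  expect_equal(trajectory_length(p[1:k, ]) + trajectory_length(p[k:100, ]),
               trajectory_length(p))
})

test_that("sparc equals the brute-force direct-DFT oracle", {
  set.seed(123)
  for (i in 1:50) {
    fs <- 50
    n <- sample(120:300, 1)
    v <- 1.5 + band_noise(n, fs, amp = 0.4, f_lo = 0.3, f_hi = 8)
    expect_equal(sparc(v, fs), sparc_brute(v, fs), tolerance = 1e-9)
  }
})

test_that("sparc is invariant to time reversal and amplitude scaling", {
  set.seed(5)
  v <- 1.2 + band_noise(200, 50, amp = 0.3)
  expect_equal(sparc(rev(v), 50), sparc(v, 50))
  expect_equal(sparc(3.7 * v, 50), sparc(v, 50))
  expect_lte(sparc(v, 50), 0)
})

test_that("sparc rejects degenerate inputs", {
  expect_error(sparc(rep(0, 100), 50), "spectrum undefined")
  expect_error(sparc(1:5, 50), "at least 8")
  expect_error(sparc(rep(1, 100), 15), "sampling_rate")
  expect_error(sparc(rep(1, 100), 50, v_threshold = 1.5), "v_threshold")
})

test_that("entropy matches closed forms on exact bin fixtures", {
  # all samples within one 1-degree bin
  expect_equal(shannon_entropy(runif(100, 10.1, 10.9)), 0)
  # exactly uniform over 16 distinct bins
  expect_equal(shannon_entropy(rep(0:15 + 0.5, each = 25)), 4)
  expect_error(shannon_entropy(numeric(0)), "empty")
  expect_error(shannon_entropy(c(1, NaN)), "finite")
})

test_that("entropy matches an independent histogram recount and its bound", {
  set.seed(11)
  a <- rnorm(10000, 0, 5)
  # independent recount: bin occupancy by explicit counting
  bins <- unique(floor(a))
  counts <- vapply(bins, function(b) sum(a >= b & a < b + 1), numeric(1))
  p <- counts / length(a)
  expect_equal(shannon_entropy(a), -sum(p * log2(p)), tolerance = 1e-12)
  expect_lte(shannon_entropy(a), log2(length(bins)))
  # invariant to full turns
  expect_equal(shannon_entropy(a + 360), shannon_entropy(a))
})

test_that("collision episodes are counted on rising edges", {
  expect_equal(collision_count(c(0, 1, 1, 0, 1)), 2)
  expect_equal(collision_count(rep(0, 10)), 0)
  expect_equal(collision_count(c(1, 1, 0)), 1)
  expect_equal(completion_time(c(0, 91.7, 183.4)), 183.4)
})

test_that("compute_metrics reproduces a hand-computed fixture", {
  tr <- hand_trial()
  m <- compute_metrics(tr, sampling_rate = 50)
  expect_equal(m$completion_time, 0.18)
  expect_equal(m$n_collisions, 2L)
  # straight line at constant speed is degree-1, so smoothing is exact
  expect_equal(m$L, 0.18, tolerance = 1e-9)
  expect_equal(m$H_pitch, 0)   # constant pitch: single bin
  expect_equal(m$H_chi, 0)     # yaws locked equal
  # SPARC of the (constant) smoothed speed profile vs the independent oracle
  expect_equal(m$SPARC, sparc_brute(rep(1, 9), 50), tolerance = 1e-9)
})

test_that("added heading noise lowers SPARC in simulated trials", {
  wk <- default_walker_params()
  wk$hesitation_rate <- 0
  quiet <- wk
  quiet$sigma_speed[] <- 0.03
  noisy <- wk
  noisy$sigma_speed[] <- 0.25
  set.seed(21)
  lower <- replicate(20, {
    cfgq <- fast_config(walker = quiet)
    cfgn <- fast_config(walker = noisy)
    vq <- compute_metrics(simulate_trial(condition = "none", config = cfgq),
                          cfgq$sampling_rate)$SPARC
    vn <- compute_metrics(simulate_trial(condition = "none", config = cfgn),
                          cfgn$sampling_rate)$SPARC
    vn < vq
  })
  expect_gte(mean(lower), 0.95)
})
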