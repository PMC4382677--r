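test_that("transfer function matches closed form, limit and monotonicity", {
  p <- network_params()
  expect_equal(transfer_rate(0.4, p), 1 / p$d, tolerance = 1e-6)
  expect_equal(transfer_rate(0.6, p), 54 / (1 - exp(-p$d * 54)),
               tolerance = 1e-10)
  expect_equal(transfer_rate(0.2, p), -54 / (1 - exp(p$d * 54)),
               tolerance = 1e-10)
  I <- seq(-0.5, 1.5, length.out = 4001)
  r <- transfer_rate(I, p)
  expect_true(all(r >= 0))
  expect_true(all(diff(r) > 0))
  # continuity through the removable singularity
  eps <- c(-1e-7, -1e-9, 0, 1e-9, 1e-7)
  expect_true(max(abs(transfer_rate(0.4 + eps, p) - 1 / p$d)) < 1e-3)
  expect_error(transfer_rate(NaN, p), "non-finite")
})

test_that("ring coupling has Gaussian profile with angle wrapping", {
  expect_equal(gaussian_coupling(90, 90, 1.2, -0.3, 43.2), 1.2)
  expect_equal(gaussian_coupling(0, 43.2, 1, 0, 43.2), exp(-0.5),
               tolerance = 1e-12)
  expect_equal(angle_dist(10, 350), 20)
  expect_equal(gaussian_coupling(10, 350, 1, -1, 43.2),
               gaussian_coupling(0, 20, 1, -1, 43.2))
  G <- coupling_matrix(16, 0.9, -0.2, 43.2)
  expect_equal(diag(G), rep(0.9, 16))
  expect_equal(G, t(G))
})

test_that("recurrent current normalizes by presynaptic count", {
  expect_equal(recurrent_current(c(0.1, 0.2, 0.3),
                                 matrix(1, 1, 3)), 0.2)
  s0 <- rep(0.4, 5)
  G <- matrix(0.7, 5, 5)
  expect_equal(recurrent_current(s0, G), rep(0.7 * 0.4, 5))
  expect_equal(recurrent_current(rep(0, 5), G), rep(0, 5))
  expect_error(recurrent_current(rep(0.1, 4), G), "dim|length")
})

test_that("OU noise: deterministic decay, stationary SD and correlation time", {
  # sigma_n = 0: pure exponential decay
  x <- 0.02
  for (i in 1:10) x <- ou_noise_step(x, dt = 1, tau_n = 2, sigma_n = 0, z = 0)
  expect_equal(x, 0.02 * exp(-10 / 2), tolerance = 1e-12)
  # stationary SD and lag-tau_n autocorrelation over many parallel chains
  set.seed(42)
  n <- 20000
  x <- rnorm(n, 0, 0.009) # start at stationarity
  lag2 <- NULL
  for (t in 1:40) {
    if (t == 39) lag2 <- x
    x <- ou_noise_step(x, dt = 1, tau_n = 2, sigma_n = 0.009)
  }
  expect_equal(sd(x), 0.009, tolerance = 0.03)
  expect_equal(cor(lag2, x), exp(-1), tolerance = 0.05)
  expect_lt(abs(mean(x)), 3 * 0.009 / sqrt(n))
})

test_that("compiled normal sampler is sound", {
  z <- zig_normals(7, 5e5)
  expect_lt(abs(mean(z)), 0.006)
  expect_equal(sd(z), 1, tolerance = 0.01)
  expect_equal(mean(z^4), 3, tolerance = 0.1)        # kurtosis
  expect_equal(mean(abs(z) > 3), 0.0027, tolerance = 0.2) # tails
  expect_identical(zig_normals(11, 10), zig_normals(11, 10))
})

test_that("gating step: fixed point, exact decay, second-order accuracy", {
  p <- network_params()
  s_star <- 0.641 * 20 * 0.06 / (1 + 0.641 * 20 * 0.06)
  expect_equal(s_star, 0.4348, tolerance = 1e-4)
  s <- 0.1
  for (i in 1:5000) s <- gating_step(s, 20, 1, p)
  expect_equal(s, s_star, tolerance = 1e-6)
  # r = 0: Heun approximates exponential decay with O(dt^2) local error
  s1 <- gating_step(0.5, 0, 1, p)
  exact1 <- 0.5 * exp(-1 / p$tau_s)
  s_half <- gating_step(gating_step(0.5, 0, 0.5, p), 0, 0.5, p)
  # halving dt roughly quarters the error
  expect_lt(abs(s_half - exact1), 0.3 * abs(s1 - exact1))
  # bounds hold for arbitrary nonnegative rates
  set.seed(1)
  s <- runif(50)
  for (i in 1:200) {
    s <- gating_step(s, runif(50, 0, 500), 1, p)
    expect_true(all(s >= 0 & s <= 1))
  }
})

test_that("R reference step and C++ engine integrate identically (noise off)", {
  p <- small_params(sigma_n = 0)
  ts <- task_spec()
  set.seed(5)
  w <- init_weights(p)
  n_steps <- 120
  # R reference: accumulate stimulus-period rates over a short "trial"
  st <- init_state(p)
  cpl <- catcircuit:::effective_couplings(w, p)
  stim <- stimulus_current(ring_directions(p$n_sensory), 75, ts$g_s, ts$sigma_s)
  accA <- 0
  for (t in 1:n_steps) {
    out <- step_network(st, w, p,
                        ext = list(I_sens = stim, I_dec = ts$gating_current),
                        couplings = cpl, noise = FALSE)
    st <- out$state
    accA <- accA + out$r_assoc
  }
  # engine: same protocol (no pre-stimulus, no intertrial)
  ts2 <- task_spec(t_prestim = 0, t_stim = n_steps, t_iti = 0, t_reset = 0,
                   window = 25)
  tr <- run_trial(init_state(p), w, 75, p, ts2, noise = FALSE, seed = 1)
  expect_equal(tr$rates$assoc, accA / n_steps, tolerance = 1e-4)
})

test_that("deterministic engine is reproducible and symmetric", {
  p <- small_params()
  ts <- task_spec()
  set.seed(8)
  w <- init_weights(p)
  st <- init_state(p)
  a <- run_trial(st, w, 45, p, ts, seed = 33)
  b <- run_trial(st, w, 45, p, ts, seed = 33)
  expect_identical(a$rates, b$rates)
  expect_identical(a$choice, b$choice)
  # exact C1/C2 symmetry with noise off: identical decision trajectories
  p0 <- small_params(sigma_n = 0)
  w$c_ad[] <- 0.5
  w$c_da[] <- 0.5
  tr <- run_trial(init_state(p0), w, 45, p0, ts, noise = FALSE, seed = 1,
                  record = 1)
  expect_equal(tr$trace_dec[, 1], tr$trace_dec[, 2], tolerance = 1e-9)
  expect_identical(tr$choice, "invalid")
})
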