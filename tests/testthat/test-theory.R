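test_that("covariance decomposition: worked examples and error handling", {
  expect_equal(as.numeric(covariance_decomposition(
    choice_spec(c(0.5, 0.5), c(1, 0), c(55, 50)))), 1.25)
  expect_equal(as.numeric(covariance_decomposition(
    choice_spec(c(0.5, 0.3, 0.2), c(1, 0, 0), c(10, 5, 2)))), 1.55)
  expect_equal(as.numeric(covariance_decomposition(
    choice_spec(c(0.3, 0.7), c(1, 0), c(40, 40)))), 0)
  expect_error(choice_spec(c(0.5, 0.4), c(1, 0), c(1, 2)), "sum to 1")
})

test_that("general n-choice form reduces exactly to the two-choice product", {
  set.seed(21)
  for (i in 1:200) {
    P1 <- runif(1, 0.01, 0.99)
    spec <- choice_spec(c(P1, 1 - P1), rnorm(2, 0.5, 0.5), rnorm(2, 30, 15))
    v <- covariance_decomposition(spec)
    expect_lt(abs(as.numeric(v) - attr(v, "two_choice")),
              1e-12 * max(1, abs(as.numeric(v))))
  }
})

test_that("Monte-Carlo oracle agrees with the closed form", {
  set.seed(22)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    P <- runif(k); P <- P / sum(P)
    spec <- choice_spec(P, runif(k), runif(k, 0, 60))
    mc <- mc_covariance_oracle(spec, n_samples = 4e4,
                               rate_sd = sample(c(0, 5), 1))
    expect_lt(abs(mc$cov - covariance_decomposition(spec)), 4 * mc$se + 1e-12)
  }
  # deterministic R and N: zero covariance
  mc <- mc_covariance_oracle(choice_spec(c(.5, .5), c(1, 1), c(10, 10)), 1e4)
  expect_equal(mc$cov, 0, tolerance = 1e-12)
})

test_that("Gaussian choice probability: closed form and empirical ROC", {
  expect_equal(cp_gaussian(55, 50, 5), pnorm(5 / (5 * sqrt(2))),
               tolerance = 1e-12)
  expect_equal(round(cp_gaussian(55, 50, 5), 4), 0.7602)
  expect_equal(cp_gaussian(50, 50, 3), 0.5)
  expect_equal(cp_gaussian(50, 55, 5), 1 - cp_gaussian(55, 50, 5))
  expect_error(cp_gaussian(1, 2, 0), "positive")
  set.seed(23)
  n <- 2e5
  emp <- roc_area(rnorm(n, 55, 5), rnorm(n, 50, 5))
  expect_equal(emp, 0.7602, tolerance = 2e-3)
})

test_that("toy neuron drifts at the covariance-predicted rate", {
  # (55, 50): drift q * P1 P2 (R1 - R2)(N1 - N2) = 3.75e-5 per trial
  w <- toy_neuron_run(55, 50, n_trials = 1500, n_repeats = 120, seed = 31)
  expect_equal(attr(w, "drift_theory"), 3.75e-5)
  settle <- 50 # let the reward EMA reach its mean
  drift <- mean(w[1501, ] - w[settle, ]) / (1500 - settle + 1)
  expect_equal(drift, 3.75e-5, tolerance = 0.2)
  # symmetric depression for the swapped pair
  w2 <- toy_neuron_run(50, 55, n_trials = 1500, n_repeats = 120, seed = 32)
  drift2 <- mean(w2[1501, ] - w2[settle, ]) / (1500 - settle + 1)
  expect_equal(drift2, -3.75e-5, tolerance = 0.2)
  # CP = 0.5: no systematic drift, random-walk variance growth
  w0 <- toy_neuron_run(50, 50, n_trials = 2000, n_repeats = 200, seed = 33)
  d0 <- w0[2001, ] - w0[1, ]
  expect_lt(abs(mean(d0)), 2 * sd(d0) / sqrt(length(d0)))
  v_half <- var(w0[1001, ] - w0[1, ])
  v_full <- var(d0)
  expect_gt(v_full / v_half, 1.4) # roughly linear growth
})
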