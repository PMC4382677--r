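test_that("Hebbian update: worked example, gating by RPE, clipping", {
  expect_equal(hebbian_update(0.5, 20, 30, R = 1, R_expected = 0.5, q = 3e-5),
               0.509)
  expect_equal(hebbian_update(0.42, 50, 50, R = 1, R_expected = 1, q = 3e-5),
               0.42)
  expect_equal(hebbian_update(0.999, 100, 100, R = 1, R_expected = 0, q = 3e-5),
               1)
  expect_equal(hebbian_update(0.001, 100, 100, R = 0, R_expected = 1, q = 3e-5),
               0)
  # matrix form is the outer product over (post, pre)
  c0 <- matrix(0.5, 2, 3)
  up <- hebbian_update(c0, r_pre = c(1, 2, 3), r_post = c(10, 20),
                       R = 1, R_expected = 0.5, q = 1e-3)
  expect_equal(up, pmin(c0 + 1e-3 * 0.5 * outer(c(10, 20), c(1, 2, 3)), 1))
})

test_that("reward tracker: EMA form, convergence, per-stimulus independence", {
  tr <- new_reward_tracker()
  expect_equal(get_reward_expectation(tr, 15), 0.5)
  tr <- update_reward_expectation(tr, 15, 1, tau_r = 5)
  expect_equal(get_reward_expectation(tr, 15), 0.6)
  for (i in 1:200) tr <- update_reward_expectation(tr, 15, 1, tau_r = 5)
  expect_equal(get_reward_expectation(tr, 15), 1, tolerance = 1e-8)
  expect_equal(get_reward_expectation(tr, 45), 0.5) # untouched stimulus
  tr <- update_reward_expectation(tr, 45, 0, tau_r = 5)
  expect_equal(get_reward_expectation(tr, 45), 0.4)
  expect_equal(get_reward_expectation(tr, 15), 1, tolerance = 1e-8)
  expect_error(update_reward_expectation(tr, 15, 0.3))
})

test_that("weight initialization: profile, ranges, reproducibility", {
  p <- network_params()
  set.seed(3)
  w <- init_weights(p)
  # c_sa maximal where preferred directions match
  expect_true(all(abs(apply(w$c_sa, 2, which.max) - seq_len(128)) %in%
                    c(0, 1, 127)))
  expect_equal(max(w$c_sa), p$c_sa_peak)
  expect_true(all(w$c_ad >= 0.25 & w$c_ad <= 0.75))
  expect_true(all(w$c_da >= 0.25 & w$c_da <= 0.75))
  expect_equal(mean(w$c_ad), 0.5, tolerance = 0.03)
  set.seed(3)
  w2 <- init_weights(p)
  expect_identical(w, w2)
  expect_null(init_weights(p, "no_feedback")$c_da)
})

test_that("end-of-trial update: validity gate, sparsity, variant freezing", {
  p <- small_params()
  set.seed(4)
  w <- init_weights(p)
  tr <- new_reward_tracker()
  rates <- list(sens = runif(p$n_sensory, 0, 30),
                assoc = runif(p$n_assoc, 0, 30), dec = c(40, 5))
  # invalid trial: bitwise unchanged
  up <- end_of_trial_update(w, rates, R = 1, tr, 15, p, valid = FALSE)
  expect_identical(up$weights, w)
  expect_identical(up$tracker, tr)
  # all-zero rates: no change regardless of reward
  z <- list(sens = rates$sens * 0, assoc = rates$assoc * 0, dec = c(0, 0))
  up <- end_of_trial_update(w, z, R = 1, tr, 15, p, valid = TRUE)
  expect_equal(up$weights$c_sa, w$c_sa)
  expect_equal(up$weights$c_ad, w$c_ad)
  # single active pre/post pair touches exactly one synapse of c_sa
  one <- z
  one$sens[3] <- 10; one$assoc[7] <- 10
  up <- end_of_trial_update(w, one, R = 1, tr, 15, p, valid = TRUE)
  d <- up$weights$c_sa != w$c_sa
  expect_equal(which(d),
               which(outer(seq_len(p$n_assoc) == 7,
                           seq_len(p$n_sensory) == 3) > 0))
  # fixed_tuning: c_sa frozen, c_ad still plastic
  wf <- init_weights(p, "fixed_tuning")
  up <- end_of_trial_update(wf, rates, R = 1, tr, 15, p, valid = TRUE)
  expect_identical(up$weights$c_sa, wf$c_sa)
  expect_false(identical(up$weights$c_ad, wf$c_ad))
  # tracker updates after the weights (RPE uses pre-trial expectation)
  tr2 <- update_reward_expectation(new_reward_tracker(), 15, 1, p$tau_r)
  up <- end_of_trial_update(w, rates, R = 1, tr2, 15, p, valid = TRUE)
  manual <- hebbian_update(w$c_sa, rates$sens, rates$assoc, 1,
                           get_reward_expectation(tr2, 15), p$q_sa)
  expect_equal(up$weights$c_sa, manual)
})

test_that("expected weight drift equals q Cov[R, N | theta]", {
  # toy two-choice setting: fixed stimulus, P(C1) = 0.6, reward iff C1,
  # N = r_pre * r_post with choice-dependent post rate
  set.seed(9)
  q <- 1e-5
  P1 <- 0.6
  n_post <- c(30, 22) # rate for choice C1 / C2
  r_pre <- 10
  spec <- choice_spec(c(P1, 1 - P1), c(1, 0), r_pre * n_post)
  expected <- q * as.numeric(covariance_decomposition(spec))
  n <- 4e5
  c1 <- runif(n) < P1
  R <- as.numeric(c1)
  dc <- q * (R - P1) * r_pre * ifelse(c1, n_post[1], n_post[2])
  # holding R_expected at <R|theta> = P1, far from the clip bounds
  expect_equal(mean(dc), expected, tolerance = 4 * sd(dc) / sqrt(n) / abs(expected))
  # update order within a trial does not matter (shared pre-update RPE)
  p <- small_params()
  w <- init_weights(p)
  rates <- list(sens = runif(p$n_sensory, 0, 30),
                assoc = runif(p$n_assoc, 0, 30), dec = c(40, 5))
  tr <- new_reward_tracker()
  up <- end_of_trial_update(w, rates, 1, tr, 15, p)
  e0 <- get_reward_expectation(tr, 15)
  expect_equal(up$weights$c_da,
               hebbian_update(w$c_da, rates$dec, rates$assoc, 1, e0, p$q_da))
})

test_that("weight bounds survive randomized fuzzing", {
  p <- small_params(q_sa = 5e-3, q_ad = 5e-3, q_da = 5e-3)
  set.seed(11)
  w <- init_weights(p)
  tr <- new_reward_tracker()
  for (i in 1:60) {
    rates <- list(sens = runif(p$n_sensory, 0, 80),
                  assoc = runif(p$n_assoc, 0, 80),
                  dec = runif(2, 0, 80))
    th <- sample(task_spec()$directions, 1)
    up <- end_of_trial_update(w, rates, R = rbinom(1, 1, 0.5), tr, th, p)
    w <- up$weights; tr <- up$tracker
  }
  expect_true(all(w$c_sa >= 0 & w$c_sa <= 1))
  expect_true(all(w$c_ad >= 0 & w$c_ad <= 1))
  expect_true(all(w$c_da >= 0 & w$c_da <= 1))
  expect_true(all(unlist(tr) >= 0 & unlist(tr) <= 1))
})
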