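test_that("stimulus current: peak, width and wrap-around", {
  pref <- ring_directions(128)
  expect_equal(stimulus_current(30, 30), 0.1)
  expect_equal(stimulus_current(120, 30), 0.1 * exp(-90^2 / (2 * 43.2^2)))
  expect_equal(round(stimulus_current(120, 30), 4), 0.0114)
  expect_equal(stimulus_current(210, 30), 0.1 * exp(-180^2 / (2 * 43.2^2)))
  expect_lt(stimulus_current(210, 30), 2e-5)
  expect_equal(stimulus_current(350, 10), stimulus_current(10, 350))
})

test_that("category assignment and boundary distance", {
  expect_equal(assign_category(c(15, 195, 345), 0), c("C1", "C2", "C2"))
  expect_equal(assign_category(105, 90), "C1")
  expect_error(assign_category(180, 0), "boundary")
  expect_error(assign_category(90, 90), "boundary")
  expect_equal(boundary_distance(c(15, 165, 195, 345), 0), c(15, 15, 15, 15))
  expect_equal(boundary_distance(c(75, 105), 0), c(75, 75))
  # the 12 task directions sit at 15/45/75 degrees from the boundary
  expect_setequal(boundary_distance(task_spec()$directions, 0), c(15, 45, 75))
})

test_that("decision readout applies the threshold rules", {
  expect_equal(read_decision(c(25, 5)), "C1")
  expect_equal(read_decision(c(5, 25)), "C2")
  expect_equal(read_decision(c(25, 25)), "invalid")
  expect_equal(read_decision(c(5, 5)), "invalid")
  expect_equal(read_decision(c(25, 5), prestim_cross = TRUE), "invalid")
  expect_equal(read_decision(c(19.9, 20.1), threshold = 20), "C2")
})

test_that("psychometric summary: exact fractions on a hand-built log", {
  log12 <- data.frame(
    trial = 1:12,
    theta_deg = c(15, 15, 45, 45, 75, 75, 195, 195, 225, 255, 345, 105),
    valid = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE,
              TRUE, TRUE),
    reward = c(1, 0, 1, 1, 1, 1, 0, NA, 1, 1, 1, 0))
  ps <- psychometric(log12)
  # 15-deg bin: valid trials at 15, 15, 195, 345 -> rewards 1, 0, 0, 1
  expect_equal(unname(ps$by_distance["15deg"]), 50)
  # 45-deg bin: 45, 45, 225 -> 1, 1, 1
  expect_equal(unname(ps$by_distance["45deg"]), 100)
  # 75-deg bin: 75, 75, 255, 105 -> 1, 1, 1, 0
  expect_equal(unname(ps$by_distance["75deg"]), 75)
  expect_equal(ps$overall, 100 * 8 / 11)
  expect_equal(ps$n_valid, 11)
  # all-correct and alternating logs
  log12$reward <- ifelse(log12$valid, 1, NA)
  expect_equal(psychometric(log12)$overall, 100)
  ps50 <- psychometric(data.frame(trial = 1:8, theta_deg = rep(15, 8),
                                  valid = TRUE, reward = rep(c(1, 0), 4)))
  expect_equal(ps50$overall, 50)
  expect_true(is.na(ps50$by_distance["45deg"]))
})

test_that("training bookkeeping: frozen pathways and q = 0", {
  p <- small_params(q_sa = 0, q_ad = 0, q_da = 0)
  r <- train("feedback", 25, p, seed = 5, snapshots = c(0, 10, 25))
  expect_equal(r$snapshots[["0"]]$c_sa, r$snapshots[["25"]]$c_sa)
  expect_equal(r$snapshots[["0"]]$c_ad, r$snapshots[["25"]]$c_ad)
  expect_equal(r$snapshots[["10"]]$c_da, r$weights$c_da)
  p2 <- small_params()
  rf <- train("fixed_tuning", 40, p2, seed = 6, snapshots = c(0, 40))
  expect_identical(rf$snapshots[["0"]]$c_sa, rf$snapshots[["40"]]$c_sa)
  expect_null(rf$weights$c_da)
  expect_false(identical(rf$snapshots[["0"]]$c_ad, rf$weights$c_ad))
})

test_that("fully biased decision weights force the choice deterministically", {
  p <- small_params(sigma_n = 0)
  set.seed(21)
  w <- init_weights(p)
  w$c_ad[1, ] <- 1; w$c_ad[2, ] <- 0  # all drive to the C1 population
  tr <- run_trial(init_state(p), w, 255, p, task_spec(), noise = FALSE,
                  seed = 4)
  expect_identical(tr$choice, "C1")
  w$c_ad[1, ] <- 0; w$c_ad[2, ] <- 1
  tr2 <- run_trial(init_state(p), w, 255, p, task_spec(), noise = FALSE,
                   seed = 4)
  expect_identical(tr2$choice, "C2")
})

test_that("compiled and reference training loops agree trial by trial", {
  p <- small_params(sigma_n = 0)
  a <- train("feedback", 25, p, seed = 9, engine = "cpp")
  b <- train("feedback", 25, p, seed = 9, engine = "r")
  expect_identical(a$trials$theta_deg, b$trials$theta_deg)
  expect_identical(a$trials$choice, b$trials$choice)
  expect_equal(a$trials$reward_expectation, b$trials$reward_expectation,
               tolerance = 1e-12)
  expect_equal(a$weights$c_sa, b$weights$c_sa, tolerance = 1e-12)
  expect_equal(a$weights$c_ad, b$weights$c_ad, tolerance = 1e-12)
  expect_equal(a$weights$c_da, b$weights$c_da, tolerance = 1e-12)
  # same seed reproduces the full run
  a2 <- train("feedback", 25, p, seed = 9)
  expect_identical(a$trials, a2$trials)
})

test_that("frozen evaluation never mutates weights and samples uniformly", {
  p <- small_params()
  set.seed(10)
  w <- init_weights(p)
  h <- digest_weights <- function(w) sum(w$c_sa) + sum(w$c_ad) + sum(w$c_da)
  before <- h(w)
  ev <- frozen_evaluation(w, 360, p, seed = 11)
  expect_identical(h(w), before)
  expect_s3_class(ev, "rate_dataset")
  counts <- table(ev$trials$theta_deg)
  expect_equal(length(counts), 12)
  expect_gt(suppressWarnings(chisq.test(counts)$p.value), 1e-4)
  expect_equal(dim(ev$rates), c(360, p$n_assoc))
  # labels are consistent: correct = choice matches category on valid trials
  v <- ev$trials$valid
  expect_equal(ev$trials$correct[v],
               (ev$trials$choice == ev$trials$category)[v])
})
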