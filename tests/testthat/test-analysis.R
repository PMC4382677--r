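test_that("ROC area: worked examples, ties, complement and invariance", {
  expect_equal(roc_area(c(3, 5), c(1, 2)), 1)
  expect_equal(roc_area(c(1, 3), c(2, 4)), 0.25)
  expect_equal(roc_area(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(roc_area(c(1, 1), c(1, 1)), 0.5) # ties get half credit
  set.seed(1)
  x <- rnorm(40); y <- rnorm(35, 0.5)
  expect_equal(roc_area(x, y), 1 - roc_area(y, x), tolerance = 1e-12)
  expect_equal(roc_area(exp(x), exp(y)), roc_area(x, y)) # monotone transform
  expect_error(roc_area(numeric(0), 1), "empty")
})

test_that("CTI: step tuning, flat tuning and brute-force pair oracle", {
  dirs <- task_spec()$directions
  cats <- assign_category(dirs, 0)
  step <- as.numeric(cats == "C1")
  expect_equal(cti(step, dirs), 1)
  expect_equal(cti(rep(2, 12), dirs), 0)
  # brute-force oracle over all 66 pairs, grouped by angular separation
  r <- c(2, 1, 0, 0, 1, 2, 0, 0, 0, 0, 0, 0)
  d_b <- list(); d_w <- list()
  for (i in 1:11) for (j in (i + 1):12) {
    sep <- as.character(angle_dist(dirs[i], dirs[j]))
    d <- abs(r[i] - r[j])
    if (cats[i] == cats[j]) d_w[[sep]] <- c(d_w[[sep]], d)
    else d_b[[sep]] <- c(d_b[[sep]], d)
  }
  seps <- intersect(names(d_b), names(d_w))
  bcd <- mean(sapply(d_b[seps], mean))
  wcd <- mean(sapply(d_w[seps], mean))
  expect_equal(cti(r, dirs), (bcd - wcd) / (bcd + wcd))
  # a purely direction-tuned population averages to zero CTI
  bell <- sapply(seq(0, 345, 15), function(th0)
    cti(catcircuit:::dir_profile(dirs, 1, 10, 1.3, th0), dirs, 0))
  expect_lt(abs(mean(bell)), 0.02)
  # invariance under positive affine rate transforms
  set.seed(2)
  rr <- runif(12, 1, 5)
  expect_equal(cti(3 * rr + 10, dirs), cti(rr, dirs), tolerance = 1e-12)
  expect_gt(cti(step, dirs), 0)
  # alternating profile phase-flipped across the boundary: neighbours differ
  # within categories but agree across the boundary -> negative CTI
  expect_lt(cti(c(0, 10, 0, 10, 0, 10, 10, 0, 10, 0, 10, 0), dirs), 0)
})

make_choice_dataset <- function(n_per = 40, cp = 0.76, sd = 5, seed = 5,
                                tuning = NULL) {
  # one neuron; rates Gaussian with choice-conditioned shift calibrated to cp
  set.seed(seed)
  dirs <- task_spec()$directions
  theta <- rep(dirs, each = n_per)
  cats <- assign_category(theta, 0)
  pc1 <- plogis(0.05 * ifelse(cats == "C1", 1, -1) * boundary_distance(theta))
  choice <- ifelse(runif(length(theta)) < pc1, "C1", "C2")
  delta <- sqrt(2) * sd * qnorm(cp)
  mu <- if (is.null(tuning)) 50 else tuning[match(theta, dirs)]
  rates <- rnorm(length(theta), mu + delta * ifelse(choice == "C1", .5, -.5), sd)
  rate_dataset(matrix(rates, ncol = 1), theta, choice, boundary = 0)
}

test_that("category sensitivity: separable rates, shuffles and rank invariance", {
  dirs <- task_spec()$directions
  tun <- ifelse(assign_category(dirs, 0) == "C1", 10, 1)
  ds <- make_choice_dataset(30, cp = 0.5, sd = 0.01, tuning = tun)
  expect_equal(category_sensitivity(ds, 1), 1)
  ds2 <- ds
  ds2$rates <- log(ds2$rates + 5) # monotone transform
  expect_equal(category_sensitivity(ds2, 1), category_sensitivity(ds, 1))
  # permuting rates across trials destroys category selectivity
  set.seed(6)
  ds$rates <- ds$rates[sample(nrow(ds$rates)), , drop = FALSE]
  expect_lt(abs(category_sensitivity(ds, 1) - 0.5), 0.08)
})

test_that("choice probability: inclusion rules and estimator consistency", {
  ds <- make_choice_dataset(200, cp = 0.76, sd = 5, seed = 7)
  cp <- choice_probability(ds, 1, details = TRUE)
  expect_equal(as.numeric(cp), 0.76, tolerance = 0.03)
  per <- attr(cp, "per_stimulus")
  expect_true(all(per$n_c1 >= 3 & per$n_c2 >= 3))
  # stimuli with < 3 minority-choice trials are excluded from the average
  ds2 <- make_choice_dataset(6, cp = 0.76, sd = 5, seed = 8)
  cp2 <- choice_probability(ds2, 1, details = TRUE)
  per2 <- attr(cp2, "per_stimulus")
  if (!is.null(per2)) expect_true(all(per2$n_c1 >= 3 & per2$n_c2 >= 3))
  # a neuron without qualifying stimuli in both categories is missing
  one_sided <- ds
  keep <- ds$trials$category == "C1"
  ds3 <- rate_dataset(ds$rates[keep, , drop = FALSE],
                      ds$trials$theta_deg[keep], ds$trials$choice[keep])
  expect_true(is.na(choice_probability(ds3, 1)))
  # choice-independent rates give CP near 0.5
  ds0 <- make_choice_dataset(100, cp = 0.5, seed = 9)
  expect_lt(abs(choice_probability(ds0, 1) - 0.5), 0.05)
})

test_that("CP shuffle test: null calibration and power", {
  p_null <- replicate(25, {
    ds <- make_choice_dataset(25, cp = 0.5, seed = sample.int(1e6, 1))
    cp_shuffle_test(ds, 1, n_shuffles = 120)$p
  })
  expect_gte(mean(p_null > 0.05), 0.8)
  ds <- make_choice_dataset(60, cp = 0.9, seed = 10)
  expect_lt(cp_shuffle_test(ds, 1, n_shuffles = 300)$p, 0.001)
})

test_that("choice inference from match/nonmatch responses", {
  expect_equal(infer_choice_from_match("C1", "match", 45), "C1")
  expect_equal(infer_choice_from_match("C1", "nonmatch", 75), "C2")
  expect_equal(infer_choice_from_match("C2", "match", 75), "C2")
  expect_equal(infer_choice_from_match("C2", "nonmatch", 45), "C1")
  expect_equal(infer_choice_from_match("C1", "match", 15), "excluded")
  expect_equal(infer_choice_from_match(c("C1", "C2"), c("match", "match"),
                                       c(45, 15)), c("C1", "excluded"))
})

test_that("noise correlations: duplicates, null scaling and hand example", {
  set.seed(11)
  n <- 400
  theta <- rep(task_spec()$directions, length.out = n)
  base <- rnorm(n)
  rates <- cbind(a = base + rnorm(n, 0, 1e-6), b = base, c = rnorm(n))
  ds <- rate_dataset(rates + 20, theta,
                     choice = assign_category(theta, 0)) # all correct
  rsc <- noise_correlations(ds)
  expect_equal(rsc["1", "2"], 1, tolerance = 1e-6) # duplicated neuron
  expect_lt(abs(rsc["1", "3"]), 3 / sqrt(n))       # independent neuron
  # hand-computed 2-neuron, 2-stimulus, 4-trials-each example
  th <- rep(c(15, 45), each = 4)
  r1 <- c(1, 2, 3, 4, 10, 12, 11, 13)
  r2 <- c(2, 1, 4, 3, 10, 14, 12, 12)
  ds2 <- rate_dataset(cbind(r1, r2), th, choice = rep("C1", 8))
  manual <- mean(c(cor(r1[1:4], r2[1:4]), cor(r1[5:8], r2[5:8])))
  expect_equal(noise_correlations(ds2)[1, 2], manual)
  # zero-variance neuron within a stimulus: that stimulus is skipped
  r3 <- c(5, 5, 5, 5, 1, 2, 3, 5)
  ds3 <- rate_dataset(cbind(r1, r3), th, choice = rep("C1", 8))
  expect_equal(noise_correlations(ds3)[1, 2], cor(r1[5:8], r3[5:8]))
})
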