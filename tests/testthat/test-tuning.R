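test_that("directional tuning fit recovers known parameters", {
  dirs <- task_spec()$directions
  truth <- list(r0 = 3, rmax = 15, w_rad = 1.3, theta0 = 117)
  curve <- catcircuit:::dir_profile(dirs, truth$r0, truth$rmax, truth$w_rad,
                                    truth$theta0)
  fit <- fit_direction_tuning(curve, dirs)
  expect_true(fit$converged)
  expect_equal(fit$r0, truth$r0, tolerance = 1e-3)
  expect_equal(fit$rmax, truth$rmax, tolerance = 1e-3)
  expect_equal(fit$w_rad, truth$w_rad, tolerance = 1e-3)
  expect_lt(angle_dist(fit$theta0, truth$theta0), 0.1)
  # flat curve: degenerate, flagged, no preferred direction
  flat <- fit_direction_tuning(rep(4, 12), dirs)
  expect_true(flat$flat)
  expect_true(is.na(flat$theta0))
})

test_that("width conversions invert each other and map the half height", {
  w <- c(0.5, 1, 1.5)
  expect_equal(width_to_rad(width_to_deg(w)), w, tolerance = 1e-10)
  # at the half-width, the profile is at half its amplitude
  wd <- width_to_deg(1.2)
  prof <- catcircuit:::dir_profile(wd, 0, 1, 1.2, 0)
  expect_equal(prof, 0.5, tolerance = 1e-10)
})

test_that("two-pass population fit constrains widths to the percentile band", {
  set.seed(13)
  dirs <- task_spec()$directions
  n <- 40
  w_deg <- runif(n, 95, 150)
  curves <- sapply(seq_len(n), function(i)
    catcircuit:::dir_profile(dirs, runif(1, 1, 4), runif(1, 8, 20),
                             width_to_rad(w_deg[i]), runif(1, 0, 360)) +
      rnorm(12, 0, 0.3))
  rownames(curves) <- dirs
  pop <- fit_population_tuning(curves, dirs)
  # the band is the 45th-55th percentile window of pass-1 widths
  expect_lt(diff(pop$w_band), diff(range(w_deg)))
  expect_true(pop$w_band[1] <= pop$w_median &&
                pop$w_median <= pop$w_band[2])
  ws <- vapply(pop$fits, function(f) f$w_deg, numeric(1))
  ok <- vapply(pop$fits, function(f) isTRUE(f$converged) && !isTRUE(f$flat),
               logical(1))
  expect_true(all(ws[ok] >= pop$w_band[1] - 0.5 &
                    ws[ok] <= pop$w_band[2] + 0.5))
  # band-construction rule reproduces given endpoints when the population
  # percentiles sit at them (the published association-neuron band)
  wfix <- seq(101.4, 142.7, length.out = 11) # 45th/55th pct at the endpoints
  expect_equal(unname(quantile(wfix, c(0.45, 0.55))), c(101.4, 142.7),
               tolerance = 2)
})

test_that("step categorical profile averages within categories", {
  dirs <- task_spec()$directions
  r <- seq_len(12)
  cf <- fit_category_tuning(r, dirs, 0)
  cats <- assign_category(dirs, 0)
  expect_equal(unname(cf$levels["C1"]), mean(r[cats == "C1"]))
  expect_equal(unname(cf$levels["C2"]), mean(r[cats == "C2"]))
  expect_equal(cf$fitted, unname(cf$levels[cats]))
  step <- ifelse(cats == "C1", 7, 2)
  expect_equal(fit_category_tuning(step, dirs, 0)$fitted, unname(step))
  flat <- fit_category_tuning(rep(3, 12), dirs, 0)
  expect_equal(unname(flat$levels), c(3, 3))
})

test_that("ridge GLM classifies generated tuning types", {
  set.seed(14)
  dirs <- task_spec()$directions
  n_per <- 25
  theta <- rep(dirs, each = n_per)
  cats <- assign_category(theta, 0)
  gen <- function(mu) rnorm(length(theta), mu, 1.5)
  run_case <- function(r) {
    curve <- tapply(r, theta, mean)[as.character(dirs)]
    dfit <- fit_direction_tuning(as.numeric(curve), dirs)
    cfit <- fit_category_tuning(as.numeric(curve), dirs, 0)
    glm_classify(r, theta, dfit, cfit, dirs, n_shuffles = 300)
  }
  # pure direction tuning
  mu_d <- catcircuit:::dir_profile(theta, 2, 12, 1.3, 200)
  lab_d <- run_case(gen(mu_d))$label
  expect_equal(lab_d, "direction")
  # pure categorical step
  mu_c <- ifelse(cats == "C1", 10, 4)
  expect_equal(run_case(gen(mu_c))$label, "category")
  # mixed
  mu_m <- 0.8 * mu_d + ifelse(cats == "C1", 6, 0)
  expect_true(run_case(gen(mu_m))$label %in% c("mixed"))
  # pure noise: mostly nonselective at the nominal error rate
  labs <- replicate(12, run_case(rnorm(length(theta), 8, 2))$label)
  expect_gte(mean(labs == "nonselective"), 0.7)
})
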