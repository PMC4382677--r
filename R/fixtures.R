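#' Specification of a synthetic rate dataset with known ground truth
#'
#' Describes a population of synthetic neurons with known tuning (directional
#' exponential-cosine, categorical step, mixed, or flat), known per-neuron
#' choice probability (implemented as a choice-conditioned Gaussian mean
#' shift), a shared-gain factor inducing uniform noise correlations, and a
#' logistic psychometric rule generating choices (so error trials exist at
#' every boundary distance, as the CP inclusion rules require).
#'
#' @param n_neurons number of neurons.
#' @param trials_per_stim trials per stimulus direction.
#' @param type_probs named probabilities for the tuning types
#'   (`direction`, `category`, `mixed`, `flat`); sampled per neuron.
#' @param cp_target scalar or per-neuron vector of target choice
#'   probabilities (0.5 = no choice coupling).
#' @param shared_gain_sd SD of the trial-wide shared gain (rate units); 0
#'   gives independent neurons.
#' @param noise_sd SD of the private rate noise (Hz).
#' @param psycho_slope logistic slope of P(choice = C1) in the signed
#'   boundary distance (per degree).
#' @param directions stimulus set (deg); `boundary` category boundary (deg).
#' @param seed RNG seed used by [generate_dataset()].
#' @return a `fixture_spec` object.
#' @export
fixture_spec <- function(n_neurons = 60, trials_per_stim = 40,
                         type_probs = c(direction = 0.4, category = 0.2,
                                        mixed = 0.2, flat = 0.2),
                         cp_target = 0.5, shared_gain_sd = 0, noise_sd = 3,
                         psycho_slope = 0.05,
                         directions = task_spec()$directions, boundary = 0,
                         seed = 1L) {
  stopifnot(all(names(type_probs) %in%
                  c("direction", "category", "mixed", "flat")),
            all(cp_target > 0 & cp_target < 1), noise_sd > 0)
  structure(list(n_neurons = n_neurons, trials_per_stim = trials_per_stim,
                 type_probs = type_probs / sum(type_probs),
                 cp_target = rep_len(cp_target, n_neurons),
                 shared_gain_sd = shared_gain_sd, noise_sd = noise_sd,
                 psycho_slope = psycho_slope, directions = directions,
                 boundary = boundary, seed = seed),
            class = "fixture_spec")
}

#' Generate a labeled rate dataset from a fixture specification
#'
#' Trial rates are tuning(theta) + choice-conditioned shift + shared gain +
#' private Gaussian noise. The choice-conditioned shift is
#' \eqn{\pm\delta/2} for C1/C2 choices with \eqn{\delta = \sqrt{2}\,\sigma\,
#' \Phi^{-1}(CP)} and \eqn{\sigma = \sqrt{\sigma_{noise}^2 +
#' \sigma_{gain}^2}}, so the neuron's true CP equals the target exactly under
#' the Gaussian ROC. Choices follow the logistic psychometric rule in signed
#' boundary distance. Ground truth (tuning parameters, per-neuron true CTI
#' computed from the noiseless tuning curve, true CP, tuning label) is
#' returned alongside and never consumed by the analysis code.
#'
#' @param spec a [fixture_spec()].
#' @return list: `dataset` (a [rate_dataset()]) and `truth` (data frame per
#'   neuron: type, r0, rmax, w_deg, theta0, c1_level, c2_level, cp_true,
#'   cti_true).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  dirs <- spec$directions
  nst <- length(dirs)
  n_tr <- nst * spec$trials_per_stim
  theta <- rep(dirs, each = spec$trials_per_stim)

  # choices: logistic in signed boundary distance (positive towards C1)
  cat_true <- assign_category(theta, spec$boundary)
  sdist <- ifelse(cat_true == "C1", 1, -1) *
    boundary_distance(theta, spec$boundary)
  p_c1 <- stats::plogis(spec$psycho_slope * sdist)
  choice <- ifelse(stats::runif(n_tr) < p_c1, "C1", "C2")

  types <- sample(names(spec$type_probs), spec$n_neurons, replace = TRUE,
                  prob = spec$type_probs)
  sigma_tot <- sqrt(spec$noise_sd^2 + spec$shared_gain_sd^2)
  delta <- sqrt(2) * sigma_tot * stats::qnorm(spec$cp_target)

  truth <- data.frame(neuron = seq_len(spec$n_neurons), type = types,
                      r0 = NA_real_, rmax = NA_real_, w_deg = NA_real_,
                      theta0 = NA_real_, c1_level = NA_real_,
                      c2_level = NA_real_, cp_true = spec$cp_target,
                      cti_true = NA_real_)
  rates <- matrix(NA_real_, n_tr, spec$n_neurons)
  gain <- if (spec$shared_gain_sd > 0)
    stats::rnorm(n_tr, 0, spec$shared_gain_sd) else numeric(n_tr)
  chs <- ifelse(choice == "C1", 0.5, -0.5)

  for (i in seq_len(spec$n_neurons)) {
    ty <- types[i]
    tun <- rep(0, nst)
    if (ty %in% c("direction", "mixed")) {
      truth$r0[i] <- stats::runif(1, 2, 8)
      truth$rmax[i] <- stats::runif(1, 10, 25)
      truth$w_deg[i] <- stats::runif(1, 90, 140)
      truth$theta0[i] <- stats::runif(1, 0, 360)
      tun <- dir_profile(dirs, truth$r0[i], truth$rmax[i],
                         width_to_rad(truth$w_deg[i]), truth$theta0[i])
    }
    if (ty %in% c("category", "mixed")) {
      # a categorical neuron must actually contrast the categories: draw the
      # two levels with a guaranteed separation (a zero-contrast step is flat)
      base <- stats::runif(1, 4, 10)
      sep <- stats::runif(1, 3, 8) * sample(c(-1, 1), 1)
      lv <- c(base + sep / 2, base - sep / 2)
      truth$c1_level[i] <- lv[1]; truth$c2_level[i] <- lv[2]
      tun <- tun + ifelse(assign_category(dirs, spec$boundary) == "C1",
                          lv[1], lv[2])
    }
    if (ty == "flat") {
      truth$r0[i] <- stats::runif(1, 5, 15)
      tun <- rep(truth$r0[i], nst)
    }
    # ground-truth CTI of the neuron's *expected* tuning curve, which
    # includes the choice-conditioned shift weighted by the psychometric
    # choice rates (the estimand of a raw tuning-curve CTI)
    p_c1_dir <- stats::plogis(spec$psycho_slope *
                                ifelse(assign_category(dirs, spec$boundary) ==
                                         "C1", 1, -1) *
                                boundary_distance(dirs, spec$boundary))
    exp_curve <- tun + delta[i] * (p_c1_dir - 0.5)
    truth$cti_true[i] <- tryCatch(cti(exp_curve, dirs, spec$boundary),
                                  error = function(e) NA_real_)
    mu <- tun[match(theta, dirs)]
    rates[, i] <- mu + delta[i] * chs + gain +
      stats::rnorm(n_tr, 0, spec$noise_sd)
  }
  ds <- rate_dataset(rates, theta, choice, spec$boundary)
  list(dataset = ds, truth = truth)
}

#' Estimator-recovery report on a synthetic fixture
#'
#' Runs the analysis estimators on a generated dataset and tabulates their
#' recovery of the known ground truth: bias and RMSE of CTI, CP and the
#' preferred direction, and the tuning-label confusion matrix from the
#' ridge-GLM classification. The ground truth is only used for scoring,
#' never by the estimators.
#'
#' @param fx result of [generate_dataset()].
#' @param n_shuffles shuffle-null size passed to [glm_classify()].
#' @param min_trials CP inclusion rule.
#' @return list: `per_neuron` data frame (estimates joined to truth),
#'   `summary` (bias/RMSE per quantity), `confusion` (truth x estimated
#'   label table).
#' @export
ground_truth_report <- function(fx, n_shuffles = 200, min_trials = 3) {
  ds <- fx$dataset; truth <- fx$truth
  n <- ncol(ds$rates)
  curves <- tuning_curves(ds)
  dirs <- as.numeric(rownames(curves))
  pop <- fit_population_tuning(curves, dirs)
  est <- data.frame(neuron = seq_len(n))
  est$cti_hat <- vapply(seq_len(n), function(i)
    cti(curves[, i], dirs, ds$boundary), numeric(1))
  est$cp_hat <- vapply(seq_len(n), function(i)
    choice_probability(ds, i, min_trials), numeric(1))
  est$cs_hat <- vapply(seq_len(n), function(i)
    category_sensitivity(ds, i), numeric(1))
  est$theta0_hat <- vapply(pop$fits, function(f)
    if (isTRUE(f$flat) || !isTRUE(f$converged)) NA_real_ else f$theta0,
    numeric(1))
  est$label_hat <- vapply(seq_len(n), function(i) {
    cf <- fit_category_tuning(curves[, i], dirs, ds$boundary)
    glm_classify(ds$rates[, i], ds$trials$theta_deg, pop$fits[[i]], cf,
                 dirs, n_shuffles = n_shuffles)$label
  }, character(1))
  per <- merge(truth, est, by = "neuron")
  rmse <- function(e) sqrt(mean(e^2, na.rm = TRUE))
  dth <- angle_diff(per$theta0_hat, per$theta0)
  summ <- data.frame(
    quantity = c("cti", "cp", "theta0"),
    bias = c(mean(per$cti_hat - per$cti_true, na.rm = TRUE),
             mean(per$cp_hat - per$cp_true, na.rm = TRUE),
             mean(dth, na.rm = TRUE)),
    rmse = c(rmse(per$cti_hat - per$cti_true),
             rmse(per$cp_hat - per$cp_true), rmse(dth)))
  conf <- table(truth = per$type,
                estimated = factor(per$label_hat,
                                   levels = c("direction", "category",
                                              "mixed", "nonselective")))
  list(per_neuron = per, summary = summ, confusion = conf)
}
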