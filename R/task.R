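#' Stimulus current to a sensory unit
#'
#' \eqn{I_s = g_s \exp(-\Delta^2 / 2\sigma_s^2)} with \eqn{\Delta} the wrapped
#' distance between the unit's preferred direction and the stimulus direction.
#'
#' @param theta_pref preferred direction(s), deg.
#' @param theta_s stimulus direction, deg.
#' @param g_s peak current (nA); `sigma_s` width (deg).
#' @return current(s) in nA.
#' @export
stimulus_current <- function(theta_pref, theta_s, g_s = 0.1, sigma_s = 43.2) {
  g_s * exp(-angle_dist(theta_pref, theta_s)^2 / (2 * sigma_s^2))
}

#' Category membership of a direction
#'
#' C1 is the half-circle counter-clockwise of the boundary axis:
#' wrapped(theta - boundary) in (0, 180) gives C1, in (180, 360) gives C2.
#'
#' @param theta direction(s), deg.
#' @param boundary boundary axis, deg.
#' @return factor-like character vector, "C1" or "C2".
#' @export
#' @examples
#' assign_category(c(15, 195, 345), 0)
assign_category <- function(theta, boundary = 0) {
  d <- (theta - boundary) %% 360
  if (any(d %% 180 == 0))
    stop("assign_category: direction lies on the category boundary")
  ifelse(d < 180, "C1", "C2")
}

#' Decision readout from the two decision populations
#'
#' The choice is the unique decision population whose mean rate over the last
#' `window` ms of the stimulus period exceeds `threshold`. The trial is
#' invalid if both or neither population reaches threshold, or if either
#' population crossed threshold before stimulus onset.
#'
#' @param window_means numeric length-2: mean rates (C1, C2) over the readout
#'   window (Hz).
#' @param prestim_cross logical: did either population reach threshold during
#'   the pre-stimulus period?
#' @param threshold rate threshold (Hz).
#' @return `"C1"`, `"C2"` or `"invalid"`.
#' @export
#' @examples
#' read_decision(c(25, 5))   # "C1"
#' read_decision(c(25, 25))  # "invalid"
read_decision <- function(window_means, prestim_cross = FALSE, threshold = 20) {
  stopifnot(length(window_means) == 2)
  if (prestim_cross) return("invalid")
  up <- window_means > threshold
  if (sum(up) != 1) "invalid" else c("C1", "C2")[up]
}

# internal: flat parameter list consumed by the C++ engine
engine_par <- function(params, task, seed, noise_on = TRUE, record = 0L) {
  list(gamma = params$gamma, tau_s = params$tau_s, a = params$a, b = params$b,
       d = params$d, tau_n = params$tau_n, sigma_n = params$sigma_n,
       dt = params$dt, I0_sens = params$I0_sens, I0_assoc = params$I0_assoc,
       I0_dec = params$I0_dec, gating_current = task$gating_current,
       reset_current = task$reset_current,
       n_pre = as.integer(round(task$t_prestim / params$dt)),
       n_stim = as.integer(round(task$t_stim / params$dt)),
       n_iti = as.integer(round(task$t_iti / params$dt)),
       n_reset = as.integer(round(task$t_reset / params$dt)),
       n_window = as.integer(round(task$window / params$dt)),
       threshold = task$threshold, noise_on = noise_on, seed = seed,
       record = as.integer(record))
}

new_trial_seed <- function() {
  # drawn from R's RNG so that everything reproduces from one set.seed()
  sample.int(.Machine$integer.max, 1)
}

#' Simulate one task trial
#'
#' Integrates the full network through pre-stimulus, stimulus and intertrial
#' periods (C++ engine), applies the stimulus current to sensory units and
#' the gating/reset currents to the decision populations, and reads out the
#' decision.
#'
#' @param state a `network_state` carried over from the previous trial.
#' @param weights a `plastic_weights` object.
#' @param theta_s stimulus direction (deg).
#' @param params a [network_params()]; `task` a [task_spec()].
#' @param couplings optional precomputed [effective_couplings()] (the static
#'   parts are reused; plastic parts must reflect `weights`).
#' @param noise logical; simulate the OU background noise?
#' @param seed engine seed for this trial; by default drawn from R's RNG.
#' @param record 0 (default), 1 (keep decision rate traces) or 2 (keep all
#'   rate traces).
#' @return list: `choice` ("C1"/"C2"/"invalid"), `valid`, stimulus-period
#'   mean rates (`rates$sens/assoc/dec`), `window_r_dec`, `prestim_cross`,
#'   the updated `state`, and traces if requested.
#' @export
run_trial <- function(state, weights, theta_s, params = network_params(),
                      task = task_spec(), couplings = NULL, noise = TRUE,
                      seed = new_trial_seed(), record = 0L) {
  cp <- if (is.null(couplings)) effective_couplings(weights, params) else couplings
  stim <- stimulus_current(ring_directions(params$n_sensory), theta_s,
                           task$g_s, task$sigma_s)
  s0 <- c(state$s_sens, state$s_assoc, state$s_dec)
  res <- sim_trial_cpp(cp$GS, cp$GA, cp$WSA, cp$WAD, cp$WDA, cp$Jdec,
                       stim, s0, state$noise,
                       engine_par(params, task, seed, noise, record))
  nS <- params$n_sensory; nA <- params$n_assoc
  state$s_sens <- res$s_end[seq_len(nS)]
  state$s_assoc <- res$s_end[nS + seq_len(nA)]
  state$s_dec <- res$s_end[nS + nA + 1:2]
  state$noise <- res$noise_end
  choice <- read_decision(res$window_r_dec, res$prestim_cross, task$threshold)
  out <- list(choice = choice, valid = choice != "invalid",
              rates = list(sens = drop(res$mean_r_sens),
                           assoc = drop(res$mean_r_assoc),
                           dec = drop(res$mean_r_dec)),
              window_r_dec = drop(res$window_r_dec),
              prestim_cross = res$prestim_cross, state = state)
  if (record >= 1) out$trace_dec <- res$trace_dec
  if (record >= 2) { out$trace_assoc <- res$trace_assoc
                     out$trace_sens <- res$trace_sens }
  out
}

# internal: let the network settle into its spontaneous state
settle_state <- function(state, weights, params, task, couplings,
                         ms = 1000, noise = TRUE, seed = new_trial_seed()) {
  task0 <- task
  task0$t_prestim <- 0; task0$t_stim <- 1; task0$t_iti <- ms; task0$t_reset <- 0
  r <- run_trial(state, weights, theta_s = 0, params = params, task = task0,
                 couplings = couplings, noise = noise, seed = seed)
  r$state
}

#' Train a network variant on the categorization task
#'
#' Runs the full training loop: on each trial a stimulus is drawn uniformly
#' from the 12 task directions, the network is integrated, the decision is
#' read out, reward is delivered on valid correct trials, and all plastic
#' pathways present in the variant are updated by the reward-modulated
#' Hebbian rule. Weight snapshots are stored on a given schedule.
#'
#' @param variant `"feedback"` (all three plastic pathways),
#'   `"no_feedback"` (no decision-to-association feedback) or
#'   `"fixed_tuning"` (no feedback and frozen sensory-to-association
#'   synapses).
#' @param n_trials number of training trials.
#' @param params a [network_params()]; `task` a [task_spec()].
#' @param seed RNG seed for the whole run (stimulus sequence, weight
#'   initialization and all dynamical noise derive from it).
#' @param snapshots integer vector of trial indices at which to store copies
#'   of the plastic weights (0 = initialization; the final weights are always
#'   kept).
#' @param weights optional initial `plastic_weights` (default: fresh
#'   [init_weights()]).
#' @param engine `"cpp"` (the compiled training loop) or `"r"` (a pure-R
#'   reference loop over [run_trial()] and [end_of_trial_update()]; identical
#'   stimulus sequence and per-trial seeds, used for equivalence testing).
#' @return an object of class `catcircuit_run`: list with `trials` (data frame:
#'   trial, theta_deg, category, choice, valid, reward, reward_expectation),
#'   `snapshots` (named list of `plastic_weights`), final `weights`, final
#'   `state`, `tracker`, plus `params`, `task`, `variant`, `seed`.
#' @export
train <- function(variant = c("feedback", "no_feedback", "fixed_tuning"),
                  n_trials = 1000, params = network_params(),
                  task = task_spec(), seed = 1L,
                  snapshots = integer(0), weights = NULL,
                  engine = c("cpp", "r")) {
  variant <- match.arg(variant)
  engine <- match.arg(engine)
  set.seed(seed)
  if (is.null(weights)) weights <- init_weights(params, variant)
  cpl <- effective_couplings(weights, params)
  state <- init_state(params)
  state <- settle_state(state, weights, params, task, cpl)

  n <- n_trials
  theta <- sample(task$directions, n, replace = TRUE)
  trial_seeds <- sample.int(.Machine$integer.max, n, replace = TRUE)
  snaps <- list()
  if (0 %in% snapshots) snaps[["0"]] <- weights
  category <- assign_category(theta, task$boundary)

  if (engine == "cpp") {
    segs <- sort(unique(c(snapshots[snapshots > 0 & snapshots < n], n)))
    from <- 1L
    tracker0 <- rep(0.5, length(task$directions))
    choice <- character(n); reward <- numeric(n); rexp <- numeric(n)
    for (to in segs) {
      ix <- from:to
      res <- run_segment_cpp(weights, state, theta[ix], trial_seeds[ix],
                             tracker0, params, task, plastic = TRUE,
                             record_rates = 0L)
      choice[ix] <- res$choice_lab
      reward[ix] <- res$reward
      rexp[ix] <- res$rexp
      weights <- res$weights; state <- res$state; tracker0 <- res$rexp_final
      if (to %in% snapshots) snaps[[as.character(to)]] <- weights
      from <- to + 1L
    }
    tracker <- structure(tracker0, names = format(task$directions),
                         class = "reward_tracker")
    valid <- choice != "invalid"
  } else {
    tracker <- new_reward_tracker()
    choice <- character(n); valid <- logical(n)
    reward <- numeric(n); rexp <- numeric(n)
    for (i in seq_len(n)) {
      tr <- run_trial(state, weights, theta[i], params, task,
                      couplings = cpl, seed = trial_seeds[i])
      state <- tr$state
      R <- if (tr$valid) as.numeric(tr$choice == category[i]) else NA_real_
      rexp[i] <- get_reward_expectation(tracker, theta[i])
      if (tr$valid) {
        up <- end_of_trial_update(weights, tr$rates, R, tracker, theta[i],
                                  params, valid = TRUE)
        weights <- up$weights; tracker <- up$tracker
        cpl$WSA <- params$g_max_sa * weights$c_sa / params$n_sensory
        cpl$WAD <- params$g_max_ad * weights$c_ad / params$n_assoc
        if (!is.null(weights$c_da))
          cpl$WDA <- params$g_max_da * weights$c_da / 2
      }
      choice[i] <- tr$choice; valid[i] <- tr$valid; reward[i] <- R
      if (i %in% snapshots) snaps[[as.character(i)]] <- weights
    }
  }
  structure(list(
    trials = data.frame(trial = seq_len(n), theta_deg = theta,
                        category = category, choice = choice, valid = valid,
                        reward = reward, reward_expectation = rexp),
    snapshots = snaps, weights = weights, state = state, tracker = tracker,
    params = params, task = task, variant = variant, seed = seed
  ), class = "catcircuit_run")
}

# internal: one compiled train/eval segment; tracker0 is the per-direction
# reward expectation aligned with task$directions
run_segment_cpp <- function(weights, state, theta, trial_seeds, tracker0,
                            params, task, plastic = TRUE, record_rates = 0L) {
  dirs <- task$directions
  theta_idx <- match(theta, dirs)
  stopifnot(!anyNA(theta_idx))
  stim_mat <- vapply(dirs, function(d)
    stimulus_current(ring_directions(params$n_sensory), d, task$g_s,
                     task$sigma_s), numeric(params$n_sensory))
  cat_idx <- ifelse(assign_category(dirs, task$boundary) == "C1", 1L, 2L)
  variant <- attr(weights, "variant") %||% "feedback"
  par <- engine_par(params, task, seed = 0, noise_on = TRUE)
  par$g_max_sa <- params$g_max_sa; par$g_max_ad <- params$g_max_ad
  par$g_max_da <- params$g_max_da
  par$q_sa <- params$q_sa; par$q_ad <- params$q_ad; par$q_da <- params$q_da
  par$tau_r <- params$tau_r
  par$freeze_sa <- variant == "fixed_tuning"
  par$plastic <- plastic
  par$record_rates <- as.integer(record_rates)
  nS <- params$n_sensory; nA <- params$n_assoc
  GS <- coupling_matrix(nS, params$J_plus_sens, params$J_minus_sens,
                        params$sigma_conn) / nS
  GA <- coupling_matrix(nA, params$J_plus_assoc, params$J_minus_assoc,
                        params$sigma_conn) / nA
  Jdec <- matrix(c(params$J_dec_self, params$J_dec_cross,
                   params$J_dec_cross, params$J_dec_self), 2, 2)
  res <- train_loop_cpp(weights$c_sa, weights$c_ad,
                        if (is.null(weights$c_da)) matrix(0, 0, 0)
                        else weights$c_da,
                        GS, GA, Jdec, stim_mat,
                        as.integer(theta_idx), cat_idx,
                        as.numeric(trial_seeds), tracker0,
                        c(state$s_sens, state$s_assoc, state$s_dec),
                        state$noise, par)
  w <- weights
  w$c_sa <- res$c_sa; w$c_ad <- res$c_ad
  if (!is.null(weights$c_da)) w$c_da <- res$c_da
  state$s_sens <- res$s_end[seq_len(nS)]
  state$s_assoc <- res$s_end[nS + seq_len(nA)]
  state$s_dec <- res$s_end[nS + nA + 1:2]
  state$noise <- res$noise_end
  list(choice_lab = c("invalid", "C1", "C2")[res$choice + 1L],
       reward = res$reward, rexp = res$rexp, weights = w, state = state,
       rexp_final = res$rexp_final, rates_assoc = res$rates_assoc,
       rates_sens = res$rates_sens)
}

#' Frozen-weight evaluation run
#'
#' Simulates trials with plasticity disabled (weights frozen at their current
#' values) and returns the trial x neuron table of stimulus-period mean rates
#' with stimulus/choice/correctness labels — the input format of the analysis
#' toolkit.
#'
#' @param weights a `plastic_weights` object (left untouched).
#' @param n_trials number of evaluation trials.
#' @param params,task,seed as in [train()].
#' @param keep_sensory also store sensory-circuit rates (needed for the
#'   sensory-population MDS)?
#' @return a [rate_dataset()] whose `rates` matrix holds association-neuron
#'   rates; sensory rates, if kept, are in `attr(, "rates_sens")`.
#' @export
frozen_evaluation <- function(weights, n_trials = 2000,
                              params = network_params(), task = task_spec(),
                              seed = 1L, keep_sensory = FALSE) {
  set.seed(seed)
  cpl <- effective_couplings(weights, params)
  state <- init_state(params)
  state <- settle_state(state, weights, params, task, cpl)
  n <- n_trials
  theta <- sample(task$directions, n, replace = TRUE)
  trial_seeds <- sample.int(.Machine$integer.max, n, replace = TRUE)
  res <- run_segment_cpp(weights, state, theta, trial_seeds,
                         rep(0.5, length(task$directions)), params, task,
                         plastic = FALSE,
                         record_rates = if (keep_sensory) 2L else 1L)
  ds <- rate_dataset(res$rates_assoc, theta = theta, choice = res$choice_lab,
                     boundary = task$boundary,
                     pref_dir = ring_directions(params$n_assoc))
  if (keep_sensory) attr(ds, "rates_sens") <- res$rates_sens
  ds
}

#' Psychometric summary of a trial log
#'
#' Percent correct among valid trials, overall and by distance of the
#' stimulus from the category boundary (15, 45, 75 degrees). Invalid trials
#' are excluded from the denominators.
#'
#' @param trials a trial data frame as produced by [train()] (needs columns
#'   `theta_deg`, `valid`, `reward`).
#' @param epoch optional integer range (length 2) of trial indices to use.
#' @param boundary the category boundary axis (deg).
#' @return list: `overall` percent correct, `by_distance` named vector for
#'   the 15/45/75-degree bins (NA marks an empty bin), `n_valid`, and the
#'   fraction of valid trials `valid_frac`.
#' @export
psychometric <- function(trials, epoch = NULL, boundary = 0) {
  if (inherits(trials, "rate_dataset")) trials <- trials$trials
  if (is.null(trials$trial)) trials$trial <- seq_len(nrow(trials))
  if (is.null(trials$reward)) trials$reward <- as.numeric(trials$correct)
  if (!is.null(epoch))
    trials <- trials[trials$trial >= epoch[1] & trials$trial <= epoch[2], ]
  dist <- boundary_distance(trials$theta_deg, boundary)
  ok <- trials$valid
  pc <- function(sel) {
    sel <- sel & ok
    if (!any(sel)) return(NA_real_)
    100 * mean(trials$reward[sel])
  }
  bins <- c(15, 45, 75)
  by_d <- vapply(bins, function(b) pc(dist == b), numeric(1))
  names(by_d) <- paste0(bins, "deg")
  list(overall = pc(rep(TRUE, nrow(trials))), by_distance = by_d,
       n_valid = sum(ok), valid_frac = mean(ok))
}

#' Distance of a direction from the category boundary
#' @param theta direction(s), deg; `boundary` boundary axis, deg.
#' @return distance in degrees within `[0, 90]`.
#' @export
boundary_distance <- function(theta, boundary = 0) {
  d <- angle_diff(theta, boundary) # (-180, 180]
  pmin(abs(d), abs(180 - abs(d)))
}
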