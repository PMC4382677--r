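#' Initialize the three plastic pathways
#'
#' The sensory-to-association matrix `c_sa` (n_assoc x n_sensory) starts as a
#' periodic Gaussian profile over the difference of preferred directions
#' (strongest between units with matched preferred directions); the
#' association-to-decision `c_ad` (2 x n_assoc) and decision-to-association
#' `c_da` (n_assoc x 2) matrices start i.i.d. uniform on `[0.25, 0.75]`.
#' All entries are synaptic strengths c in `[0, 1]`; the physical coupling of
#' a pathway is `g_max * c` (nA).
#'
#' @param params a [network_params()] object.
#' @param variant one of `"feedback"`, `"no_feedback"`, `"fixed_tuning"`.
#'   The two control variants carry no feedback pathway (`c_da = NULL`).
#' @return an object of class `plastic_weights`: list with `c_sa`, `c_ad`,
#'   `c_da` and the attribute `variant`.
#' @export
#' @examples
#' set.seed(1)
#' w <- init_weights(network_params())
#' range(w$c_ad)
init_weights <- function(params = network_params(),
                         variant = c("feedback", "no_feedback", "fixed_tuning")) {
  variant <- match.arg(variant)
  nS <- params$n_sensory; nA <- params$n_assoc
  thS <- ring_directions(nS); thA <- ring_directions(nA)
  prof <- outer(thA, thS, function(a, s)
    exp(-angle_dist(a, s)^2 / (2 * params$sigma_conn^2)))
  c_sa <- params$c_sa_base + (params$c_sa_peak - params$c_sa_base) * prof
  c_ad <- matrix(stats::runif(2 * nA, 0.25, 0.75), 2, nA)
  c_da <- if (variant == "feedback")
    matrix(stats::runif(2 * nA, 0.25, 0.75), nA, 2) else NULL
  structure(list(c_sa = c_sa, c_ad = c_ad, c_da = c_da),
            class = "plastic_weights", variant = variant)
}

#' Reward-modulated Hebbian update of one plastic pathway
#'
#' \eqn{c' = \mathrm{clip}(c + q (R - \langle R|\theta\rangle)
#' r_{post} r_{pre}, 0, 1)}. `r_pre` and `r_post` are trial-averaged
#' stimulus-period rates; the update is an outer product over all synapses of
#' the pathway (rows = postsynaptic units).
#'
#' @param c matrix (post x pre) or scalar of synaptic strengths in `[0,1]`.
#' @param r_pre,r_post presynaptic / postsynaptic trial-average rates (Hz).
#' @param R reward (0 or 1); `R_expected` the stimulus-specific reward
#'   expectation at trial time; `q` learning rate.
#' @return updated strengths, clipped to `[0, 1]`.
#' @export
#' @examples
#' hebbian_update(0.5, 20, 30, R = 1, R_expected = 0.5, q = 3e-5) # 0.509
hebbian_update <- function(c, r_pre, r_post, R, R_expected, q) {
  stopifnot(q >= 0)
  rpe <- R - R_expected
  upd <- if (length(r_pre) == 1 && length(r_post) == 1) r_post * r_pre
         else outer(as.numeric(r_post), as.numeric(r_pre))
  pmin(pmax(c + q * rpe * upd, 0), 1)
}

#' Stimulus-specific reward-expectation tracker
#'
#' One first-order exponential moving average per distinct stimulus:
#' \eqn{E' = E + (R - E)/\tau_R}. Unseen stimuli start at 0.5 (chance reward
#' for a two-alternative task).
#'
#' @return `new_reward_tracker()`: an empty tracker (named numeric vector).
#' @rdname reward_tracker
#' @export
new_reward_tracker <- function() {
  structure(numeric(0), class = "reward_tracker")
}

#' @param tracker a reward tracker.
#' @param theta stimulus label (direction in degrees).
#' @rdname reward_tracker
#' @return `get_reward_expectation()`: the current expectation for `theta`.
#' @export
get_reward_expectation <- function(tracker, theta) {
  key <- format(theta)
  if (key %in% names(tracker)) unname(tracker[[key]]) else 0.5
}

#' @param R observed reward (0 or 1).
#' @param tau_r averaging time constant in trials.
#' @rdname reward_tracker
#' @return `update_reward_expectation()`: the updated tracker.
#' @export
#' @examples
#' tr <- new_reward_tracker()
#' tr <- update_reward_expectation(tr, 15, R = 1, tau_r = 5)
#' get_reward_expectation(tr, 15) # 0.6
update_reward_expectation <- function(tracker, theta, R, tau_r = 5) {
  stopifnot(R %in% c(0, 1))
  key <- format(theta)
  e <- get_reward_expectation(tracker, theta)
  tracker[[key]] <- e + (R - e) / tau_r
  class(tracker) <- "reward_tracker"
  tracker
}

#' End-of-trial plasticity update
#'
#' Applies the reward-modulated Hebbian rule to every plastic pathway using
#' the trial's stimulus-period mean rates and the shared reward-prediction
#' error `R - <R|theta>`, then updates the reward tracker (so the RPE always
#' uses the pre-trial expectation). Invalid trials trigger no plasticity and
#' leave the tracker untouched. The `fixed_tuning` variant freezes `c_sa`;
#' variants without a feedback pathway have no `c_da` to update.
#'
#' @param weights a `plastic_weights` object.
#' @param rates list with numeric vectors `sens`, `assoc`, `dec`
#'   (trial-averaged stimulus-period rates, Hz).
#' @param R reward (0/1); ignored when `valid` is FALSE.
#' @param tracker a reward tracker; `theta` the trial's stimulus.
#' @param params a [network_params()] object (learning rates, `tau_r`).
#' @param valid logical; was the trial's decision valid?
#' @return list with updated `weights` and `tracker`.
#' @export
end_of_trial_update <- function(weights, rates, R, tracker, theta,
                                params = network_params(), valid = TRUE) {
  if (!valid) return(list(weights = weights, tracker = tracker))
  e <- get_reward_expectation(tracker, theta)
  variant <- attr(weights, "variant")
  if (is.null(variant)) variant <- "feedback"
  if (variant != "fixed_tuning")
    weights$c_sa <- hebbian_update(weights$c_sa, rates$sens, rates$assoc,
                                   R, e, params$q_sa)
  weights$c_ad <- hebbian_update(weights$c_ad, rates$assoc, rates$dec,
                                 R, e, params$q_ad)
  if (!is.null(weights$c_da))
    weights$c_da <- hebbian_update(weights$c_da, rates$dec, rates$assoc,
                                   R, e, params$q_da)
  tracker <- update_reward_expectation(tracker, theta, R, params$tau_r)
  list(weights = weights, tracker = tracker)
}
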