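#' Choice-conditioned specification of a task
#'
#' The ingredients of the covariance decomposition of the reward-modulated
#' Hebbian rule: for one stimulus, the probability of each choice, the
#' expected reward given each choice, and the expected neural activity
#' (product of pre- and postsynaptic trial rates) given each choice.
#'
#' @param P choice probabilities (sum to 1).
#' @param R expected reward per choice.
#' @param N expected neural activity per choice.
#' @return a `choice_spec` object.
#' @export
choice_spec <- function(P, R, N) {
  stopifnot(length(P) == length(R), length(R) == length(N), all(P >= 0))
  if (abs(sum(P) - 1) > 1e-8) stop("choice probabilities must sum to 1")
  structure(list(P = P, R = R, N = N), class = "choice_spec")
}

#' Covariance between reward and neural activity, decomposed by choice
#'
#' Computes \eqn{\mathrm{Cov}[R, N \mid \theta]} from choice-conditioned
#' expectations: the general n-choice form
#' \eqn{\sum_i P_i R_i N_i - (\sum_i P_i R_i)(\sum_i P_i N_i)}, and for
#' two-choice tasks the equivalent product form
#' \eqn{P_1 P_2 (R_1 - R_2)(N_1 - N_2)}. With two choices both are computed
#' and verified to agree (an algebraic identity); the general form is
#' returned.
#'
#' @param spec a [choice_spec()].
#' @return the covariance, with attribute `two_choice` (the product form)
#'   when `length(spec$P) == 2`.
#' @export
#' @examples
#' covariance_decomposition(choice_spec(c(.5, .5), c(1, 0), c(55, 50))) # 1.25
covariance_decomposition <- function(spec) {
  stopifnot(inherits(spec, "choice_spec"))
  P <- spec$P; R <- spec$R; N <- spec$N
  gen <- sum(P * R * N) - sum(P * R) * sum(P * N)
  if (length(P) == 2) {
    two <- P[1] * P[2] * (R[1] - R[2]) * (N[1] - N[2])
    if (abs(gen - two) > 1e-10 * max(1, abs(gen)))
      stop("internal inconsistency: two-choice product form != general form")
    attr(gen, "two_choice") <- two
  }
  gen
}

#' Monte-Carlo oracle for the choice-conditioned covariance
#'
#' Samples (choice, R, N) from a [choice_spec()] — choice from P, reward
#' equal to its choice-conditional expectation, neural activity Gaussian
#' around its choice-conditional mean — and returns the sample covariance.
#' Used as a brute-force check of [covariance_decomposition()] (added
#' activity noise is independent of reward given the choice, so it does not
#' bias the covariance).
#'
#' @param spec a [choice_spec()].
#' @param n_samples number of Monte-Carlo draws (>= 1e4 for a stable check).
#' @param rate_sd SD of the activity noise around the conditional mean.
#' @return list: `cov` (sample covariance), `se` (its jackknife-free
#'   asymptotic standard error estimate), `n_samples`.
#' @export
mc_covariance_oracle <- function(spec, n_samples = 1e5, rate_sd = 0) {
  stopifnot(inherits(spec, "choice_spec"), n_samples >= 2)
  k <- sample.int(length(spec$P), n_samples, replace = TRUE, prob = spec$P)
  R <- spec$R[k]
  N <- spec$N[k] + if (rate_sd > 0) stats::rnorm(n_samples, 0, rate_sd) else 0
  cv <- stats::cov(R, N)
  # asymptotic SE of the sample covariance via the delta method
  u <- (R - mean(R)) * (N - mean(N))
  se <- stats::sd(u) / sqrt(n_samples)
  list(cov = cv, se = se, n_samples = n_samples)
}

#' Closed-form choice probability for Gaussian rate distributions
#'
#' ROC area between two equal-variance Gaussians with means `N1` (C1 choices)
#' and `N2` (C2 choices): \eqn{\Phi((N_1 - N_2) / (\sqrt{2}\,sd)}. CP > 0.5
#' means higher rates on C1-choice trials.
#'
#' @param N1,N2 mean rates (Hz) conditioned on choice C1 / C2.
#' @param sd common SD of the rate distributions (> 0).
#' @return CP in `[0, 1]`.
#' @export
#' @examples
#' cp_gaussian(55, 50, 5) # 0.7602
cp_gaussian <- function(N1, N2, sd) {
  if (any(sd <= 0)) stop("cp_gaussian: sd must be positive")
  stats::pnorm((N1 - N2) / (sqrt(2) * sd))
}

#' Toy-model neuron: synaptic drift under reward-modulated Hebbian plasticity
#'
#' A single neuron whose firing rate is sampled per trial from a Gaussian
#' with choice-dependent mean (`N1` for C1, `N2` for C2; common SD
#' `rate_sd`), with choices drawn with probability 0.5 each and reward 1 iff
#' C1 is chosen. Its synapse (initial strength 0.5, partner rate fixed at 1)
#' follows the same reward-modulated Hebbian rule as the circuit model, with
#' a single running-average reward expectation (one implicit stimulus).
#' After the reward average settles, the expected per-trial drift equals
#' \eqn{q P_1 P_2 (R_1 - R_2)(N_1 - N_2)} — the covariance decomposition —
#' so the sign and speed of synaptic change are set by how far the neuron's
#' choice probability is from 0.5.
#'
#' @param N1,N2 choice-conditioned mean rates (Hz).
#' @param n_trials trials per realization.
#' @param n_repeats independent realizations (columns of the output).
#' @param q learning rate; `tau_r` reward-average constant (trials);
#'   `rate_sd` rate SD (Hz); `c0` initial weight.
#' @param seed RNG seed.
#' @return matrix `(n_trials + 1) x n_repeats` of weight trajectories
#'   (row 1 = initial weight), with attribute `drift_theory` the closed-form
#'   expected per-trial drift (before clipping).
#' @export
toy_neuron_run <- function(N1, N2, n_trials = 1000, n_repeats = 1,
                           q = 3e-5, tau_r = 5, rate_sd = 5, c0 = 0.5,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- matrix(NA_real_, n_trials + 1, n_repeats)
  cw <- rep(c0, n_repeats)
  e <- rep(0.5, n_repeats)
  w[1, ] <- cw
  for (t in seq_len(n_trials)) {
    c1 <- stats::runif(n_repeats) < 0.5
    rate <- stats::rnorm(n_repeats, ifelse(c1, N1, N2), rate_sd)
    R <- as.numeric(c1)
    cw <- pmin(pmax(cw + q * (R - e) * rate * 1, 0), 1)
    e <- e + (R - e) / tau_r
    w[t + 1, ] <- cw
  }
  attr(w, "drift_theory") <- q * 0.25 * (1 - 0) * (N1 - N2)
  w
}
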