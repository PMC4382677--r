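#' Wrapped angular distance
#'
#' Absolute difference between two angles on the circle, wrapped to at most
#' 180 degrees.
#'
#' @param theta_i,theta_j angles in degrees.
#' @return absolute wrapped distance in `[0, 180]`.
#' @export
#' @examples
#' angle_dist(10, 350) # 20
angle_dist <- function(theta_i, theta_j) {
  abs((theta_i - theta_j + 180) %% 360 - 180)
}

#' Signed wrapped angular difference in (-180, 180]
#' @param theta,ref angles in degrees.
#' @return signed difference theta - ref wrapped to (-180, 180].
#' @export
angle_diff <- function(theta, ref) {
  d <- (theta - ref) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Effective f-I transfer function
#'
#' Firing rate as a function of total synaptic current,
#' \eqn{r(I) = (aI - b) / (1 - e^{-d(aI - b)})}. The removable singularity at
#' \eqn{aI = b} is evaluated by series expansion; the function is continuous
#' and strictly increasing, and the rate is always nonnegative.
#'
#' @param I total synaptic current (nA); vectorized.
#' @param params a [network_params()] object (uses `a`, `b`, `d`).
#' @return firing rate(s) in Hz.
#' @export
#' @examples
#' transfer_rate(0.4, network_params()) # = 1/d = 6.4935 Hz
transfer_rate <- function(I, params = network_params()) {
  if (!all(is.finite(I))) stop("transfer_rate: non-finite input current")
  x <- params$a * I - params$b
  y <- params$d * x
  r <- numeric(length(x))
  small <- abs(y) < 1e-6
  r[small] <- (1 / params$d) * (1 + y[small] / 2 + y[small]^2 / 12)
  r[!small] <- x[!small] / (1 - exp(-y[!small]))
  r
}

#' Periodic Gaussian ring coupling
#'
#' Synaptic coupling between two ring units as a function of the wrapped
#' difference of their preferred directions:
#' \eqn{g = J_- + (J_+ - J_-) \exp(-\Delta^2 / 2\sigma^2)}.
#'
#' @param theta_i,theta_j preferred directions (deg); vectorized.
#' @param J_plus,J_minus peak and baseline coupling (nA).
#' @param sigma_conn profile width (deg).
#' @return coupling in nA.
#' @export
gaussian_coupling <- function(theta_i, theta_j, J_plus, J_minus, sigma_conn) {
  dd <- angle_dist(theta_i, theta_j)
  J_minus + (J_plus - J_minus) * exp(-dd^2 / (2 * sigma_conn^2))
}

#' Ring coupling matrix
#'
#' @param n number of units (equally spaced preferred directions on 0-360).
#' @param J_plus,J_minus,sigma_conn as in [gaussian_coupling()].
#' @return n x n coupling matrix (nA), entry (i, j) = coupling from j to i.
#' @export
coupling_matrix <- function(n, J_plus, J_minus, sigma_conn) {
  th <- ring_directions(n)
  outer(th, th, gaussian_coupling, J_plus = J_plus, J_minus = J_minus,
        sigma_conn = sigma_conn)
}

#' Preferred directions of a ring of n units
#' @param n number of units.
#' @return vector of n equally spaced angles in degrees, starting at 0.
#' @export
ring_directions <- function(n) (0:(n - 1)) * 360 / n

#' Recurrent input current, normalized by presynaptic count
#'
#' @param s_pre presynaptic gating vector (entries in `[0,1]`).
#' @param G coupling matrix (post x pre, nA).
#' @param n_pre normalization count (defaults to `ncol(G)`).
#' @return current per postsynaptic unit (nA).
#' @export
recurrent_current <- function(s_pre, G, n_pre = ncol(G)) {
  if (length(s_pre) != ncol(G))
    stop("recurrent_current: length(s_pre) != ncol(G)")
  drop(G %*% s_pre) / n_pre
}

#' One step of the Ornstein-Uhlenbeck background-noise current
#'
#' Exact one-step update \eqn{I' = I e^{-dt/\tau_n} + \sigma_n
#' \sqrt{1 - e^{-2 dt/\tau_n}} z}, \eqn{z \sim N(0,1)}, which has zero
#' stationary mean, stationary SD `sigma_n` and correlation time `tau_n`
#' for any step size.
#'
#' @param I_noise current noise value(s), nA.
#' @param dt step (ms); `tau_n` time constant (ms); `sigma_n` stationary SD (nA).
#' @param z optional standard-normal draw(s); defaults to `rnorm()` from R's RNG.
#' @return updated noise current(s).
#' @export
ou_noise_step <- function(I_noise, dt, tau_n, sigma_n,
                          z = stats::rnorm(length(I_noise))) {
  stopifnot(dt > 0, tau_n > 0)
  decay <- exp(-dt / tau_n)
  I_noise * decay + sigma_n * sqrt(1 - decay^2) * z
}

#' Heun update of the synaptic gating variable
#'
#' Advances \eqn{ds/dt = -s/\tau_s + (1 - s)\gamma r} by one step of the
#' explicit Heun (predictor-corrector) scheme with the firing rate held fixed
#' over the step. Time is in ms and rates in Hz, so the drive term carries a
#' factor 1e-3. The update keeps s in `[0, 1]` for any nonnegative rate.
#'
#' @param s gating value(s) in `[0,1]`; `r` rate(s) in Hz; `dt` step in ms.
#' @param params a [network_params()] object (uses `tau_s`, `gamma`).
#' @return updated gating value(s).
#' @export
gating_step <- function(s, r, dt, params = network_params()) {
  g <- params$gamma * r * 1e-3
  f <- function(x) -x / params$tau_s + (1 - x) * g
  k1 <- f(s)
  k2 <- f(s + dt * k1)
  pmin(pmax(s + dt / 2 * (k1 + k2), 0), 1)
}

#' Initial network state
#'
#' @param params a [network_params()] object.
#' @param s0 initial gating value for every population.
#' @return a `network_state` list with gating vectors `s_sens`, `s_assoc`,
#'   `s_dec` and the OU noise vector `noise` (one entry per unit, ordered
#'   sensory, association, decision).
#' @export
init_state <- function(params = network_params(), s0 = 0) {
  structure(list(
    s_sens = rep(s0, params$n_sensory),
    s_assoc = rep(s0, params$n_assoc),
    s_dec = rep(s0, 2),
    noise = rep(0, params$n_sensory + params$n_assoc + 2)
  ), class = "network_state")
}

# Effective (pre-divided) coupling matrices for the integration engine.
# GS, GA include the 1/N presynaptic normalization; plastic pathways are
# scaled by their g_max and presynaptic counts.
effective_couplings <- function(weights, params) {
  nS <- params$n_sensory; nA <- params$n_assoc
  list(
    GS = coupling_matrix(nS, params$J_plus_sens, params$J_minus_sens,
                         params$sigma_conn) / nS,
    GA = coupling_matrix(nA, params$J_plus_assoc, params$J_minus_assoc,
                         params$sigma_conn) / nA,
    WSA = params$g_max_sa * weights$c_sa / nS,
    WAD = params$g_max_ad * weights$c_ad / nA,
    WDA = if (is.null(weights$c_da)) matrix(0, nA, 2)
          else params$g_max_da * weights$c_da / 2,
    Jdec = matrix(c(params$J_dec_self, params$J_dec_cross,
                    params$J_dec_cross, params$J_dec_self), 2, 2)
  )
}

#' Advance the full network by one time step (reference implementation)
#'
#' Pure-R reference for a single dt advance of all three circuits: total
#' currents (recurrent + plastic + background + external + noise), rates via
#' [transfer_rate()], gating via [gating_step()], then the OU noise update.
#' The C++ trial engine performs exactly this sequence; with noise switched
#' off the two are tested to agree to machine precision.
#'
#' @param state a `network_state` (see [init_state()]).
#' @param weights a `plastic_weights` object (see [init_weights()]).
#' @param params a [network_params()] object.
#' @param ext external currents: list with vectors/scalars `I_sens`,
#'   `I_assoc`, `I_dec` (nA), each defaulting to 0.
#' @param couplings optional precomputed [effective_couplings()] result.
#' @param noise logical; draw OU innovations (from R's RNG)? With
#'   `noise = FALSE` the noise current decays deterministically.
#' @return list with the updated `state` and the rate vectors `r_sens`,
#'   `r_assoc`, `r_dec` used for the update.
#' @export
step_network <- function(state, weights, params = network_params(),
                         ext = list(), couplings = NULL, noise = TRUE) {
  cp <- if (is.null(couplings)) effective_couplings(weights, params) else couplings
  nS <- params$n_sensory; nA <- params$n_assoc
  eI <- function(x) if (is.null(x)) 0 else x
  noi <- state$noise
  IS <- drop(cp$GS %*% state$s_sens) + params$I0_sens + eI(ext$I_sens) +
    noi[seq_len(nS)]
  IA <- drop(cp$GA %*% state$s_assoc) + drop(cp$WSA %*% state$s_sens) +
    drop(cp$WDA %*% state$s_dec) + params$I0_assoc + eI(ext$I_assoc) +
    noi[nS + seq_len(nA)]
  ID <- drop(cp$Jdec %*% state$s_dec) + drop(cp$WAD %*% state$s_assoc) +
    params$I0_dec + eI(ext$I_dec) + noi[nS + nA + 1:2]
  rS <- transfer_rate(IS, params)
  rA <- transfer_rate(IA, params)
  rD <- transfer_rate(ID, params)
  if (any(!is.finite(c(rS, rA, rD))))
    stop("step_network: non-finite rates, integration diverged")
  state$s_sens <- gating_step(state$s_sens, rS, params$dt, params)
  state$s_assoc <- gating_step(state$s_assoc, rA, params$dt, params)
  state$s_dec <- gating_step(state$s_dec, rD, params$dt, params)
  decay <- exp(-params$dt / params$tau_n)
  if (noise) {
    state$noise <- ou_noise_step(noi, params$dt, params$tau_n, params$sigma_n)
  } else {
    state$noise <- noi * decay
  }
  list(state = state, r_sens = rS, r_assoc = rA, r_dec = rD)
}
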