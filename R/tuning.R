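#' Width conversions for the exponential-cosine tuning profile
#'
#' The directional profile is \eqn{r(\theta) = r_0 + r_{max}
#' \exp((\cos(\theta - \theta_0) - 1) / w^2)} with the width parameter `w` in
#' radians. Widths are reported in degrees as the half-width at half height:
#' the angular distance at which the profile falls to half its peak
#' amplitude, \eqn{\Delta_h = \arccos(1 - w^2 \ln 2)} (180 degrees when the
#' curve never falls to half height).
#'
#' @param w_rad width parameter (radians); `w_deg` half-width at half height
#'   (degrees).
#' @return the converted width.
#' @export
width_to_deg <- function(w_rad) {
  z <- 1 - w_rad^2 * log(2)
  ifelse(z <= -1, 180, acos(z) * 180 / pi)
}

#' @rdname width_to_deg
#' @export
width_to_rad <- function(w_deg) {
  stopifnot(all(w_deg > 0), all(w_deg <= 180))
  sqrt((1 - cos(w_deg * pi / 180)) / log(2))
}

# profile evaluators (theta, theta0 in degrees, w in radians)
dir_profile <- function(theta, r0, rmax, w_rad, theta0) {
  r0 + rmax * exp((cos((theta - theta0) * pi / 180) - 1) / w_rad^2)
}

#' Fit the exponential-cosine directional tuning profile
#'
#' Least-squares fit of \eqn{r_0 + r_{max} \exp((\cos(\theta - \theta_0) - 1)
#' / w^2)} to a tuning curve (Levenberg-Marquardt, multiple preferred-
#' direction starts; optional box constraint on the width for the
#' population's second pass).
#'
#' @param rates mean rate per direction.
#' @param directions stimulus directions (deg).
#' @param w_limits optional length-2 width bounds, degrees (half-width at
#'   half height), used for the constrained second pass.
#' @return list: `r0`, `rmax`, `w_rad`, `w_deg`, `theta0` (deg in `[0, 360)`),
#'   `rss`, `converged`, `fitted` (profile at `directions`), `flat` (TRUE if
#'   the fit degenerates to a flat curve, leaving `theta0` unidentified).
#' @export
fit_direction_tuning <- function(rates, directions = as.numeric(names(rates)),
                                 w_limits = NULL) {
  stopifnot(length(rates) == length(directions), length(rates) >= 4)
  rng <- diff(range(rates))
  if (rng < sqrt(.Machine$double.eps)) {
    return(list(r0 = mean(rates), rmax = 0, w_rad = NA_real_, w_deg = NA_real_,
                theta0 = NA_real_, rss = 0, converged = TRUE, flat = TRUE,
                fitted = rep(mean(rates), length(rates))))
  }
  wlim_rad <- if (is.null(w_limits)) c(0.05, 12) else
    sort(width_to_rad(pmax(pmin(w_limits, 180), 1e-3)))
  starts_th <- directions[order(rates, decreasing = TRUE)][1:2]
  starts_w <- pmin(pmax(c(0.8, 1.5, 2.5), wlim_rad[1]), wlim_rad[2])
  starts <- expand.grid(th0 = starts_th, w0 = unique(starts_w))
  dat <- data.frame(th = directions, r = rates)
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    th0 <- starts$th0[k]
    fit <- tryCatch(
      minpack.lm::nlsLM(
        r ~ r0 + rmax * exp((cos((th - theta0) * pi / 180) - 1) / w^2),
        data = dat,
        start = list(r0 = min(rates), rmax = rng,
                     w = starts$w0[k], theta0 = th0),
        lower = c(r0 = min(rates) - 3 * rng, rmax = 0, w = wlim_rad[1],
                  theta0 = th0 - 360),
        upper = c(r0 = max(rates) + 3 * rng, rmax = 3 * rng, w = wlim_rad[2],
                  theta0 = th0 + 360),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      cf <- stats::coef(fit)
      best <- list(r0 = unname(cf["r0"]), rmax = unname(cf["rmax"]),
                   w_rad = unname(cf["w"]),
                   w_deg = width_to_deg(unname(cf["w"])),
                   theta0 = unname(cf["theta0"]) %% 360, rss = rss,
                   converged = TRUE, flat = FALSE,
                   fitted = unname(stats::fitted(fit)))
    }
  }
  if (is.null(best)) {
    return(list(r0 = mean(rates), rmax = NA_real_, w_rad = NA_real_,
                w_deg = NA_real_, theta0 = NA_real_, rss = NA_real_,
                converged = FALSE, flat = FALSE,
                fitted = rep(mean(rates), length(rates))))
  }
  if (best$rmax < 1e-6 * max(1, rng)) best$flat <- TRUE
  best
}

#' Two-pass population fit of directional tuning
#'
#' Pass 1 fits every neuron unconstrained; the population's median width is
#' computed over converged, non-flat fits, and pass 2 refits every neuron
#' with the width box-constrained to the 10-percentile band around that
#' median (45th to 55th percentile of the pass-1 widths). The band guards
#' against nearly flat, very broad directional fits absorbing categorical
#' structure.
#'
#' @param curves matrix of tuning curves, directions x neurons (rownames =
#'   directions in degrees).
#' @param directions stimulus directions (deg).
#' @return list: `fits` (list of [fit_direction_tuning()] results, pass 2),
#'   `w_band` (degrees), `w_median` (pass-1 median width, degrees).
#' @export
fit_population_tuning <- function(curves,
                                  directions = as.numeric(rownames(curves))) {
  n <- ncol(curves)
  pass1 <- lapply(seq_len(n), function(i)
    fit_direction_tuning(curves[, i], directions))
  ws <- vapply(pass1, function(f)
    if (isTRUE(f$converged) && !isTRUE(f$flat)) f$w_deg else NA_real_,
    numeric(1))
  ws <- ws[is.finite(ws)]
  if (length(ws) < 3) {
    return(list(fits = pass1, w_band = c(NA_real_, NA_real_),
                w_median = if (length(ws)) stats::median(ws) else NA_real_))
  }
  band <- unname(stats::quantile(ws, c(0.45, 0.55)))
  fits <- lapply(seq_len(n), function(i)
    fit_direction_tuning(curves[, i], directions, w_limits = band))
  list(fits = fits, w_band = band, w_median = stats::median(ws))
}

#' Fit the step categorical tuning profile
#'
#' The categorical profile is a step function: the mean rate across stimuli
#' of each category, constant within category.
#'
#' @param rates mean rate per direction; `directions` in degrees.
#' @param boundary category boundary axis (deg).
#' @return list: `levels` (named C1/C2 means) and `fitted` (profile at
#'   `directions`).
#' @export
fit_category_tuning <- function(rates, directions = as.numeric(names(rates)),
                                boundary = 0) {
  cat <- assign_category(directions, boundary)
  lv <- c(C1 = mean(rates[cat == "C1"]), C2 = mean(rates[cat == "C2"]))
  list(levels = lv, fitted = unname(lv[cat]))
}

# closed-form ridge with exact leave-one-out CV error; the baseline
# (intercept) column is never penalized, so shuffle nulls are centred at 0
# and the mean rate cannot leak into the tuning coefficients
ridge_penalty <- function(X) {
  d <- rep(1, ncol(X))
  d[colnames(X) == "base"] <- 0
  diag(d, ncol(X))
}

ridge_loo <- function(X, y, lambda) {
  XtX <- crossprod(X)
  A <- solve(XtX + lambda * ridge_penalty(X), t(X))
  beta <- drop(A %*% y)
  H <- X %*% A
  h <- pmin(diag(H), 1 - 1e-10)
  resid <- y - drop(X %*% beta)
  loo <- resid / (1 - h)
  list(beta = beta, loo_mse = mean(loo^2))
}

#' Ridge-GLM classification of a neuron's tuning
#'
#' Regresses single-trial firing rates on three regressors — the neuron's
#' fitted directional profile, its categorical (step) profile and a constant
#' baseline — with ridge regularization,
#' \eqn{\beta = (X^T X + \lambda D)^{-1} X^T r}, where D penalizes the two
#' tuning coefficients but not the baseline (so the mean firing rate cannot
#' leak into them and shuffle nulls are centred at zero). \eqn{\lambda} is
#' chosen on a logarithmic grid by exact leave-one-trial-out
#' cross-validation. The
#' direction and category coefficients are tested against their null
#' distributions obtained by shuffling the trial order and refitting
#' (`n_shuffles` times, two-sided t-test at `alpha`); the neuron is labeled
#' `direction`, `category`, `mixed` (both significant) or `nonselective`.
#'
#' @param r per-trial rates; `theta` per-trial stimulus directions (deg).
#' @param dir_fit a [fit_direction_tuning()] result for this neuron.
#' @param cat_fit a [fit_category_tuning()] result.
#' @param directions the stimulus set the profiles were fitted on (deg).
#' @param lambda_grid ridge penalties to search.
#' @param n_shuffles shuffle-null size; `alpha` significance level.
#' @return list: `label`, `beta` (dir, cat, base), `lambda`, `p` (dir, cat),
#'   `t` statistics, `loo_mse`.
#' @export
glm_classify <- function(r, theta, dir_fit, cat_fit,
                         directions = sort(unique(theta)),
                         lambda_grid = 10^seq(-4, 2, length.out = 13),
                         n_shuffles = 1000, alpha = 0.05) {
  idx <- match(theta, directions)
  if (anyNA(idx)) stop("glm_classify: trial stimulus not in `directions`")
  X <- cbind(dir = dir_fit$fitted[idx], cat = cat_fit$fitted[idx], base = 1)
  if (stats::sd(X[, "dir"]) < 1e-12) X[, "dir"] <- 0 # flat fit carries no signal
  sv <- svd(X, nu = 0, nv = 0)$d
  lam_floor <- if (min(sv) < 1e-8 * max(sv)) 1e-4 else 0
  if (lam_floor > 0)
    warning("glm_classify: near rank-deficient design; lambda floor applied")
  fits <- lapply(pmax(lambda_grid, lam_floor), function(l) ridge_loo(X, r, l))
  mses <- vapply(fits, `[[`, numeric(1), "loo_mse")
  k <- which.min(mses)
  lambda <- max(lambda_grid[k], lam_floor)
  beta <- fits[[k]]$beta
  A <- solve(crossprod(X) + lambda * ridge_penalty(X), t(X))
  null_beta <- matrix(NA_real_, n_shuffles, 2)
  for (s in seq_len(n_shuffles)) {
    b <- drop(A %*% r[sample(length(r))])
    null_beta[s, ] <- b[1:2]
  }
  mu <- colMeans(null_beta); sdv <- apply(null_beta, 2, stats::sd)
  sdv[sdv == 0] <- Inf
  tt <- (beta[1:2] - mu) / sdv
  p <- 2 * stats::pt(-abs(tt), df = n_shuffles - 1)
  sig <- p < alpha
  label <- if (sig[1] && sig[2]) "mixed"
           else if (sig[1]) "direction"
           else if (sig[2]) "category"
           else "nonselective"
  list(label = label, beta = c(dir = beta[[1]], cat = beta[[2]],
                               base = beta[[3]]),
       lambda = lambda, p = c(dir = p[[1]], cat = p[[2]]),
       t = c(dir = tt[[1]], cat = tt[[2]]), loo_mse = mses[k])
}
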