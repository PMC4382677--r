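#' Full analysis of a rate dataset
#'
#' Applies the complete statistics battery to a trial x neuron dataset:
#' z-scoring, tuning-curve fits (two-pass directional + categorical step),
#' ridge-GLM tuning classification with shuffle significance, CTI, CS, CP
#' (with optional shuffle p), the dip test on preferred directions of
#' direction-tuned neurons, pairwise noise correlations with CS structure,
#' and classical MDS of the population representation.
#'
#' @param dataset a [rate_dataset()] (raw Hz; z-scoring is applied here for
#'   the tuning/GLM analyses, rank-based statistics are unaffected by it).
#' @param n_shuffles shuffle count for GLM coefficient significance.
#' @param cp_shuffles shuffle count for per-neuron CP significance (0 skips).
#' @param min_trials CP inclusion rule (trials per choice per stimulus).
#' @param pairs compute the pairwise noise-correlation table? (quadratic in
#'   neurons)
#' @return an `analysis_result` list: `neurons` (per-neuron data frame:
#'   label, beta_dir, beta_cat, lambda, theta0, w_deg, cti, cs, cp, cp_p),
#'   `pairs`, `mds`, `dip`, `w_band`, and `params` (the analysis settings).
#' @export
analyze_dataset <- function(dataset, n_shuffles = 200, cp_shuffles = 0,
                            min_trials = 3, pairs = TRUE) {
  zds <- zscore_dataset(dataset)
  n <- ncol(zds$rates)
  curves <- tuning_curves(zds)
  dirs <- as.numeric(rownames(curves))
  pop <- fit_population_tuning(curves, dirs)

  neurons <- data.frame(neuron = seq_len(n))
  neurons$cti <- vapply(seq_len(n), function(i)
    cti(curves[, i], dirs, dataset$boundary), numeric(1))
  neurons$cs <- vapply(seq_len(n), function(i)
    category_sensitivity(dataset, i), numeric(1))
  neurons$cp <- vapply(seq_len(n), function(i)
    choice_probability(dataset, i, min_trials), numeric(1))
  neurons$cp_p <- NA_real_
  if (cp_shuffles > 0) {
    neurons$cp_p <- vapply(seq_len(n), function(i)
      cp_shuffle_test(dataset, i, cp_shuffles, min_trials)$p, numeric(1))
  }
  gl <- lapply(seq_len(n), function(i) {
    cf <- fit_category_tuning(curves[, i], dirs, dataset$boundary)
    glm_classify(zds$rates[, i], zds$trials$theta_deg, pop$fits[[i]], cf,
                 dirs, n_shuffles = n_shuffles)
  })
  neurons$label <- vapply(gl, `[[`, character(1), "label")
  neurons$beta_dir <- vapply(gl, function(g) g$beta[["dir"]], numeric(1))
  neurons$beta_cat <- vapply(gl, function(g) g$beta[["cat"]], numeric(1))
  neurons$lambda <- vapply(gl, `[[`, numeric(1), "lambda")
  neurons$theta0 <- vapply(pop$fits, function(f)
    if (isTRUE(f$flat) || !isTRUE(f$converged)) NA_real_ else f$theta0,
    numeric(1))
  neurons$w_deg <- vapply(pop$fits, function(f)
    if (isTRUE(f$flat) || !isTRUE(f$converged)) NA_real_ else f$w_deg,
    numeric(1))

  dtuned <- neurons$theta0[neurons$label %in% c("direction", "mixed") &
                             is.finite(neurons$theta0)]
  dip <- if (length(dtuned) >= 8)
    dip_test(dtuned, dataset$boundary, n_boot = 500) else NULL

  pr <- if (pairs && !is.null(dataset$pref_dir))
    noise_correlation_pairs(dataset, cs = neurons$cs) else NULL

  pop_means <- tuning_curves(zds)
  mds <- classical_mds(pop_means)

  structure(list(neurons = neurons, pairs = pr, mds = mds, dip = dip,
                 w_band = pop$w_band,
                 params = list(n_shuffles = n_shuffles,
                               cp_shuffles = cp_shuffles,
                               min_trials = min_trials,
                               cp_test = "cp shuffle t-test",
                               zscored = TRUE)),
            class = "analysis_result")
}

#' @export
print.analysis_result <- function(x, ...) {
  cat(sprintf("analysis_result: %d neurons\n", nrow(x$neurons)))
  print(table(x$neurons$label))
  cat(sprintf("mean CTI = %.3f; mean CP = %.3f (%d with valid CP)\n",
              mean(x$neurons$cti, na.rm = TRUE),
              mean(x$neurons$cp, na.rm = TRUE),
              sum(is.finite(x$neurons$cp))))
  if (!is.null(x$dip))
    cat(sprintf("dip test on preferred directions: D = %.4f, p = %.3f\n",
                x$dip$statistic, x$dip$p))
  cat(sprintf("MDS axis ratio = %.2f\n", x$mds$axis_ratio))
  invisible(x)
}
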