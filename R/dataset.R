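#' Trial x neuron rate dataset
#'
#' The common container consumed by every analysis operation: a trials x
#' neurons matrix of stimulus-period mean firing rates together with
#' per-trial labels (stimulus direction, true category, choice, validity,
#' correctness) and optional per-neuron labels (initial preferred direction
#' for model neurons).
#'
#' @param rates numeric matrix, trials x neurons (Hz, or z-scored units).
#' @param theta per-trial stimulus direction (deg).
#' @param choice per-trial choice: "C1", "C2" or "invalid".
#' @param boundary category boundary axis (deg); used to derive the true
#'   category and correctness.
#' @param pref_dir optional per-neuron preferred directions (deg).
#' @param zscored logical flag recording whether `rates` are z-scores.
#' @return an object of class `rate_dataset`: list with `rates`, data frame
#'   `trials` (theta_deg, category, choice, valid, correct), `pref_dir`,
#'   `boundary`, `zscored`.
#' @export
rate_dataset <- function(rates, theta, choice, boundary = 0, pref_dir = NULL,
                         zscored = FALSE) {
  rates <- as.matrix(rates)
  stopifnot(nrow(rates) == length(theta), length(theta) == length(choice))
  category <- assign_category(theta, boundary)
  valid <- choice %in% c("C1", "C2")
  correct <- ifelse(valid, choice == category, NA)
  structure(list(
    rates = rates,
    trials = data.frame(theta_deg = theta, category = category,
                        choice = choice, valid = valid, correct = correct),
    pref_dir = pref_dir, boundary = boundary, zscored = zscored
  ), class = "rate_dataset")
}

#' @export
print.rate_dataset <- function(x, ...) {
  cat(sprintf("rate_dataset: %d trials x %d neurons (%s)\n",
              nrow(x$rates), ncol(x$rates),
              if (isTRUE(x$zscored)) "z-scored" else "Hz"))
  cat(sprintf("  valid trials: %d (%.1f%%), stimuli: %d directions, boundary %g deg\n",
              sum(x$trials$valid), 100 * mean(x$trials$valid),
              length(unique(x$trials$theta_deg)), x$boundary))
  invisible(x)
}

#' Z-score a rate dataset per neuron
#'
#' Standardizes each neuron's rates across all its trials (the normalization
#' applied to recorded neurons before tuning analysis). Zero-variance neurons
#' are left at 0.
#'
#' @param dataset a [rate_dataset()].
#' @return the dataset with z-scored rates and `zscored = TRUE`.
#' @export
zscore_dataset <- function(dataset) {
  m <- colMeans(dataset$rates)
  s <- apply(dataset$rates, 2, stats::sd)
  s[s == 0] <- 1
  dataset$rates <- sweep(sweep(dataset$rates, 2, m), 2, s, "/")
  dataset$zscored <- TRUE
  dataset
}

#' Mean tuning curve(s) from a rate dataset
#'
#' Average rate per stimulus direction for each neuron, over all trials or
#' valid trials only.
#'
#' @param dataset a [rate_dataset()].
#' @param neurons column indices (default all).
#' @param valid_only average over valid trials only?
#' @return matrix directions x neurons with rownames the sorted directions.
#' @export
tuning_curves <- function(dataset, neurons = seq_len(ncol(dataset$rates)),
                          valid_only = FALSE) {
  keep <- if (valid_only) dataset$trials$valid else rep(TRUE, nrow(dataset$rates))
  th <- sort(unique(dataset$trials$theta_deg))
  out <- vapply(th, function(t) {
    sel <- keep & dataset$trials$theta_deg == t
    colMeans(dataset$rates[sel, neurons, drop = FALSE])
  }, numeric(length(neurons)))
  out <- if (length(neurons) == 1) matrix(out, ncol = 1) else t(out)
  rownames(out) <- format(th)
  out
}
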