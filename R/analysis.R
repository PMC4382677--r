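#' ROC area between two rate samples
#'
#' Area under the ROC curve for discriminating sample `x` from sample `y`:
#' \eqn{P(x > y) + \frac{1}{2} P(x = y)} over all pairs (the rank-sum
#' formulation, with half credit for ties). 1 means every `x` exceeds every
#' `y`; 0.5 means complete overlap.
#'
#' @param x,y numeric rate samples (nonempty).
#' @return area in `[0, 1]`.
#' @export
#' @examples
#' roc_area(c(3, 5), c(1, 2)) # 1
#' roc_area(c(1, 3), c(2, 4)) # 0.25
roc_area <- function(x, y) {
  if (!length(x) || !length(y)) stop("roc_area: empty sample")
  r <- rank(c(x, y))
  nx <- as.numeric(length(x)); ny <- as.numeric(length(y))
  (sum(r[seq_len(length(x))]) - nx * (nx + 1) / 2) / (nx * ny)
}

#' Category-tuning index (CTI)
#'
#' Normalized contrast of between-category versus within-category mean-rate
#' differences over direction pairs, \eqn{(BCD - WCD) / (BCD + WCD)}.
#' Pairs are compared at matched angular separations: for every separation
#' represented by both a within-category and a between-category pair, the
#' mean absolute rate difference is computed for each group, and BCD/WCD
#' average these per-separation means (separations occurring in only one
#' group — e.g. 180 degrees, always between-category — are dropped). The
#' matching removes the pure direction-tuning confound: a bell-shaped tuning
#' curve has the same expected rate difference at a given angular separation
#' whether or not the pair straddles the boundary, so a purely
#' direction-tuned population averages to CTI 0, while a step (categorical)
#' profile gives +1 and larger within- than between-category differences give
#' negative values. A flat curve returns 0.
#'
#' @param mean_rates named numeric vector: mean rate per direction (names =
#'   directions in degrees), or an unnamed vector paired with `directions`.
#' @param directions directions (deg) matching `mean_rates`.
#' @param boundary category boundary axis (deg).
#' @return index in `[-1, 1]`.
#' @export
cti <- function(mean_rates, directions = as.numeric(names(mean_rates)),
                boundary = 0) {
  stopifnot(length(mean_rates) == length(directions), length(directions) >= 2)
  cat <- assign_category(directions, boundary)
  pairs <- utils::combn(length(directions), 2)
  dif <- abs(mean_rates[pairs[1, ]] - mean_rates[pairs[2, ]])
  between <- cat[pairs[1, ]] != cat[pairs[2, ]]
  sep <- round(angle_dist(directions[pairs[1, ]], directions[pairs[2, ]]), 6)
  usable <- intersect(unique(sep[between]), unique(sep[!between]))
  if (!length(usable))
    stop("cti: no angular separation has both within- and between-category pairs")
  bcd <- mean(vapply(usable, function(d) mean(dif[between & sep == d]),
                     numeric(1)))
  wcd <- mean(vapply(usable, function(d) mean(dif[!between & sep == d]),
                     numeric(1)))
  if (bcd + wcd == 0) return(0)
  (bcd - wcd) / (bcd + wcd)
}

#' Category sensitivity (CS) of one neuron
#'
#' ROC area separating the neuron's firing-rate distributions on correct
#' trials with category-C1 versus category-C2 stimuli. 1 = strong C1
#' preference, 0 = strong C2 preference, 0.5 = no category selectivity.
#'
#' @param dataset a [rate_dataset()].
#' @param neuron column index.
#' @return CS in `[0, 1]`, or NA if either category lacks correct trials.
#' @export
category_sensitivity <- function(dataset, neuron) {
  tr <- dataset$trials
  ok <- tr$valid & tr$correct %in% TRUE
  r <- dataset$rates[, neuron]
  x <- r[ok & tr$category == "C1"]
  y <- r[ok & tr$category == "C2"]
  if (!length(x) || !length(y)) return(NA_real_)
  roc_area(x, y)
}

#' Choice probability (CP) of one neuron
#'
#' For each stimulus with at least `min_trials` valid trials for each
#' category choice, CP is the ROC area between the rate distributions on
#' C1-choice versus C2-choice trials; the neuron's CP is the unweighted mean
#' over qualifying stimuli. CP > 0.5 means higher rates predict C1 choices.
#' The estimate is reported missing (NA) unless the neuron has a qualifying
#' stimulus in each category.
#'
#' @param dataset a [rate_dataset()].
#' @param neuron column index.
#' @param min_trials minimum valid trials per choice per stimulus (default 3).
#' @param details return the per-stimulus table as an attribute?
#' @return CP in `[0, 1]` or NA (inclusion rule failed).
#' @export
choice_probability <- function(dataset, neuron, min_trials = 3,
                               details = FALSE) {
  tr <- dataset$trials
  r <- dataset$rates[, neuron]
  ths <- sort(unique(tr$theta_deg))
  per <- lapply(ths, function(th) {
    sel <- tr$valid & tr$theta_deg == th
    x <- r[sel & tr$choice == "C1"]
    y <- r[sel & tr$choice == "C2"]
    if (length(x) < min_trials || length(y) < min_trials) return(NULL)
    data.frame(theta_deg = th, category = assign_category(th, dataset$boundary),
               n_c1 = length(x), n_c2 = length(y), cp = roc_area(x, y))
  })
  per <- do.call(rbind, per)
  if (is.null(per) || !all(c("C1", "C2") %in% per$category)) {
    out <- NA_real_
  } else {
    out <- mean(per$cp)
  }
  if (details) attr(out, "per_stimulus") <- per
  out
}

#' Shuffle test for the significance of a neuron's CP
#'
#' Null distribution built by permuting choice labels within each stimulus
#' (preserving per-stimulus trial counts) and recomputing the neuron CP
#' `n_shuffles` times. The observed CP is compared against the shuffled
#' distribution with a t-style statistic, z = (CP_obs - mean_null)/sd_null,
#' and a two-sided p from the t distribution with n_shuffles - 1 df. (The
#' observed CP is a single value, so the nominal "two-sample t-test" against
#' the null sample reduces to this form; recorded as such in the output.)
#'
#' @param dataset a [rate_dataset()]; `neuron` column index.
#' @param n_shuffles number of label permutations.
#' @param min_trials CP inclusion rule, as in [choice_probability()].
#' @return list: `cp`, `p`, `z`, `null_mean`, `null_sd`, `n_shuffles`,
#'   `method`; or `p = NA` when the neuron has no valid CP.
#' @export
cp_shuffle_test <- function(dataset, neuron, n_shuffles = 1000, min_trials = 3) {
  obs <- choice_probability(dataset, neuron, min_trials)
  if (is.na(obs))
    return(list(cp = NA_real_, p = NA_real_, z = NA_real_,
                null_mean = NA_real_, null_sd = NA_real_,
                n_shuffles = n_shuffles, method = "cp shuffle t-test"))
  tr <- dataset$trials
  null_cp <- numeric(n_shuffles)
  ds <- dataset
  for (k in seq_len(n_shuffles)) {
    ch <- tr$choice
    for (th in unique(tr$theta_deg)) {
      sel <- which(tr$valid & tr$theta_deg == th)
      ch[sel] <- ch[sample(sel)]
    }
    ds$trials$choice <- ch
    null_cp[k] <- choice_probability(ds, neuron, min_trials)
  }
  mu <- mean(null_cp, na.rm = TRUE); sdv <- stats::sd(null_cp, na.rm = TRUE)
  z <- (obs - mu) / sdv
  p <- 2 * stats::pt(-abs(z), df = n_shuffles - 1)
  list(cp = obs, p = p, z = z, null_mean = mu, null_sd = sdv,
       n_shuffles = n_shuffles, method = "cp shuffle t-test")
}

#' Infer the sample-category decision from a match/nonmatch response
#'
#' For two-interval match-to-category data the subject's decision about the
#' sample category is not reported directly. When the test stimulus lies far
#' from the boundary (45 or 75 degrees), its category is assumed to be judged
#' correctly, so a "match" response implies the sample was judged to be the
#' test's category, and "nonmatch" the other category. Trials with a
#' near-boundary test (15 degrees) are excluded.
#'
#' @param test_category "C1" or "C2" (category of the test stimulus).
#' @param response "match" or "nonmatch".
#' @param test_distance distance of the test stimulus from the boundary (deg).
#' @return "C1", "C2" or "excluded"; vectorized.
#' @export
#' @examples
#' infer_choice_from_match("C1", "match", 45)    # "C1"
#' infer_choice_from_match("C1", "nonmatch", 75) # "C2"
#' infer_choice_from_match("C1", "match", 15)    # "excluded"
infer_choice_from_match <- function(test_category, response, test_distance) {
  stopifnot(all(test_category %in% c("C1", "C2")),
            all(response %in% c("match", "nonmatch")))
  other <- ifelse(test_category == "C1", "C2", "C1")
  out <- ifelse(response == "match", test_category, other)
  ifelse(test_distance %in% c(45, 75), out, "excluded")
}

#' Pairwise noise correlations
#'
#' Pearson correlation between two neurons' rates across correct trials with
#' the same stimulus, averaged across stimuli. A stimulus is skipped for a
#' pair if either neuron has zero rate variance within it (or fewer than two
#' correct trials).
#'
#' @param dataset a [rate_dataset()].
#' @param neurons column indices (default all).
#' @return symmetric matrix of average noise correlations (diagonal 1).
#' @export
noise_correlations <- function(dataset, neurons = seq_len(ncol(dataset$rates))) {
  tr <- dataset$trials
  ok <- tr$valid & tr$correct %in% TRUE
  ths <- sort(unique(tr$theta_deg))
  n <- length(neurons)
  acc <- matrix(0, n, n); cnt <- matrix(0L, n, n)
  for (th in ths) {
    sel <- ok & tr$theta_deg == th
    if (sum(sel) < 2) next
    x <- dataset$rates[sel, neurons, drop = FALSE]
    sds <- apply(x, 2, stats::sd)
    use <- sds > 0
    if (sum(use) < 2) next
    cc <- suppressWarnings(stats::cor(x[, use, drop = FALSE]))
    acc[use, use] <- acc[use, use] + cc
    cnt[use, use] <- cnt[use, use] + 1L
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  diag(out) <- 1
  dimnames(out) <- list(neurons, neurons)
  out
}

#' Pair table of noise correlations with CS structure
#'
#' Upper-triangle pairs with their noise correlation, difference in preferred
#' direction, same/different preferred category, absolute CS difference and
#' mean CS strength — the quantities against which the structure of learned
#' correlations is assessed.
#'
#' @param dataset a [rate_dataset()] with `pref_dir` set.
#' @param cs optional per-neuron CS vector (computed if missing).
#' @param rsc optional precomputed [noise_correlations()] matrix.
#' @return data frame: i, j, r_sc, d_pref (deg), same_category (logical),
#'   d_cs, cs_strength.
#' @export
noise_correlation_pairs <- function(dataset, cs = NULL, rsc = NULL) {
  if (is.null(dataset$pref_dir)) stop("dataset has no pref_dir labels")
  n <- ncol(dataset$rates)
  if (is.null(rsc)) rsc <- noise_correlations(dataset)
  if (is.null(cs)) cs <- vapply(seq_len(n), function(i)
    category_sensitivity(dataset, i), numeric(1))
  pd <- dataset$pref_dir
  pc <- assign_category(ifelse(pd %% 180 == 0, pd + 1e-6, pd), dataset$boundary)
  idx <- utils::combn(n, 2)
  i <- idx[1, ]; j <- idx[2, ]
  data.frame(i = i, j = j, r_sc = rsc[cbind(i, j)],
             d_pref = angle_dist(pd[i], pd[j]),
             same_category = pc[i] == pc[j],
             d_cs = abs(cs[i] - cs[j]),
             cs_strength = (abs(cs[i] - 0.5) + abs(cs[j] - 0.5)) / 2)
}
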