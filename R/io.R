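#' Write weight snapshots as a long-format CSV
#'
#' One row per synapse per snapshot: trial index, pathway name
#' (`c_sa`, `c_ad`, `c_da`), postsynaptic row, presynaptic column, strength.
#' A plain-text array container readable from any language.
#'
#' @param snapshots named list of `plastic_weights` (names = trial indices).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_snapshots <- function(snapshots, path) {
  rows <- lapply(names(snapshots), function(nm) {
    w <- snapshots[[nm]]
    do.call(rbind, lapply(c("c_sa", "c_ad", "c_da"), function(pw) {
      m <- w[[pw]]
      if (is.null(m)) return(NULL)
      data.frame(trial = as.integer(nm), pathway = pw,
                 post = rep(seq_len(nrow(m)), ncol(m)),
                 pre = rep(seq_len(ncol(m)), each = nrow(m)),
                 c = as.vector(m))
    }))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read weight snapshots written by [write_snapshots()]
#' @param path CSV path.
#' @return named list of `plastic_weights`.
#' @export
read_snapshots <- function(path) {
  d <- utils::read.csv(path)
  out <- list()
  for (tr in sort(unique(d$trial))) {
    w <- list()
    for (pw in unique(d$pathway[d$trial == tr])) {
      s <- d[d$trial == tr & d$pathway == pw, ]
      m <- matrix(NA_real_, max(s$post), max(s$pre))
      m[cbind(s$post, s$pre)] <- s$c
      w[[pw]] <- m
    }
    if (is.null(w$c_da)) w["c_da"] <- list(NULL)
    out[[as.character(tr)]] <- structure(w, class = "plastic_weights")
  }
  out
}

#' Write / read a rate dataset as CSV
#'
#' Columns: trial, theta_deg, category, choice, valid, correct, then one
#' rate column per neuron (`r1`, `r2`, ...).
#'
#' @param dataset a [rate_dataset()]; `path` CSV path.
#' @return `path` invisibly / the restored [rate_dataset()].
#' @export
write_rate_dataset <- function(dataset, path) {
  r <- dataset$rates
  colnames(r) <- paste0("r", seq_len(ncol(r)))
  utils::write.csv(cbind(trial = seq_len(nrow(r)), dataset$trials, r), path,
                   row.names = FALSE)
  invisible(path)
}

#' @param boundary,pref_dir metadata not stored in the CSV (boundary defaults
#'   to 0; preferred directions optional).
#' @rdname write_rate_dataset
#' @export
read_rate_dataset <- function(path, boundary = 0, pref_dir = NULL) {
  d <- utils::read.csv(path)
  rc <- grep("^r[0-9]+$", names(d))
  rate_dataset(as.matrix(d[, rc]), theta = d$theta_deg, choice = d$choice,
               boundary = boundary, pref_dir = pref_dir)
}
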