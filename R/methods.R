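#' @export
print.catcircuit_run <- function(x, ...) {
  cat(sprintf("catcircuit_run: variant '%s', %d trials (seed %d)\n",
              x$variant, nrow(x$trials), x$seed))
  ps <- psychometric(x$trials, boundary = x$task$boundary)
  cat(sprintf("  valid trials: %.1f%%; %% correct (valid): %.1f\n",
              100 * ps$valid_frac, ps$overall))
  if (length(x$snapshots))
    cat("  snapshots at trials:", paste(names(x$snapshots), collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
summary.catcircuit_run <- function(object, epoch_size = 1000, ...) {
  tr <- object$trials
  n <- nrow(tr)
  ep <- split(seq_len(n), ceiling(seq_len(n) / epoch_size))
  out <- do.call(rbind, lapply(ep, function(ix) {
    ps <- psychometric(tr[ix, , drop = FALSE],
                       boundary = object$task$boundary)
    data.frame(from = min(ix), to = max(ix), pct_correct = ps$overall,
               pct_15 = ps$by_distance[["15deg"]],
               pct_45 = ps$by_distance[["45deg"]],
               pct_75 = ps$by_distance[["75deg"]],
               valid_frac = ps$valid_frac)
  }))
  rownames(out) <- NULL
  out
}

#' Learning-curve plot of a training run
#'
#' Percent correct among valid trials in non-overlapping epochs.
#'
#' @param x a `catcircuit_run`; `epoch_size` trials per point.
#' @param ... passed to [plot()].
#' @export
plot.catcircuit_run <- function(x, epoch_size = 500, ...) {
  s <- summary(x, epoch_size)
  plot((s$from + s$to) / 2, s$pct_correct, type = "b",
       xlab = "trial", ylab = "% correct (valid)",
       ylim = c(30, 100), ...)
  graphics::abline(h = 50, lty = 3)
  invisible(s)
}

#' @export
print.plastic_weights <- function(x, ...) {
  cat(sprintf("plastic_weights (variant '%s'):\n",
              attr(x, "variant") %||% "?"))
  for (pw in c("c_sa", "c_ad", "c_da")) {
    m <- x[[pw]]
    if (is.null(m)) cat(sprintf("  %s: absent\n", pw))
    else cat(sprintf("  %s: %d x %d, range [%.3f, %.3f]\n", pw,
                     nrow(m), ncol(m), min(m), max(m)))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
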