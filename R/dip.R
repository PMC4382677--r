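#' Hartigan's dip statistic
#'
#' The dip of a sample is the smallest sup-norm distance between its
#' empirical CDF and the set of unimodal CDFs. It is computed by the
#' classical iterative construction: on a shrinking candidate modal interval
#' the greatest convex minorant and least concave majorant of the empirical
#' CDF are built; the largest deviation of the empirical CDF from the hulls
#' outside the modal interval, and the hull-to-hull gap when the interval can
#' no longer shrink, give twice the dip. The statistic is invariant under
#' affine transformations of the data (unimodality of a density is not
#' preserved by general monotone relabelings, so neither is the dip) and is
#' at least `1/(2n)`.
#'
#' @param x numeric sample (length >= 4 for a nontrivial value).
#' @return the dip statistic.
#' @export
#' @examples
#' dip_stat(seq(0, 1, length.out = 50)) # = 1/100, perfectly uniform grid
dip_stat <- function(x) {
  x <- sort(as.numeric(x))
  n <- length(x)
  if (n < 1) stop("dip_stat: empty sample")
  if (n < 4 || x[1] == x[n]) return(1 / (2 * n))
  lo <- (0:(n - 1)) / n # jump bottoms
  hi <- (1:n) / n       # jump tops

  # lower convex hull of (x, lo) over index range, using for duplicated x
  # only the admissible extreme point (min lo for the minorant, max hi for
  # the majorant); returns original indices of the hull vertices.
  lower_hull <- function(from, to) {
    keep <- from:to
    keep <- keep[!duplicated(x[keep])] # first occurrence = min lo
    h <- integer(0)
    for (i in keep) {
      while (length(h) >= 2) {
        a <- h[length(h) - 1]; b <- h[length(h)]
        # drop b if it lies on/above segment a--i (cross product test)
        if ((x[b] - x[a]) * (lo[i] - lo[a]) -
            (lo[b] - lo[a]) * (x[i] - x[a]) <= 0) h <- h[-length(h)]
        else break
      }
      h <- c(h, i)
    }
    h
  }
  upper_hull <- function(from, to) {
    keep <- from:to
    keep <- rev(keep)[!duplicated(rev(x[keep]))] # last occurrence = max hi
    keep <- rev(keep)
    h <- integer(0)
    for (i in keep) {
      while (length(h) >= 2) {
        a <- h[length(h) - 1]; b <- h[length(h)]
        if ((x[b] - x[a]) * (hi[i] - hi[a]) -
            (hi[b] - hi[a]) * (x[i] - x[a]) >= 0) h <- h[-length(h)]
        else break
      }
      h <- c(h, i)
    }
    h
  }
  interp <- function(xs, ys, xq) { # piecewise-linear, xs strictly increasing
    stats::approx(xs, ys, xout = xq, rule = 2, ties = "ordered")$y
  }

  low <- 1L; high <- n; D <- 0
  repeat {
    g <- lower_hull(low, high)
    l <- upper_hull(low, high)
    Gx <- x[g]; Gy <- lo[g]
    Lx <- x[l]; Ly <- hi[l]
    Gat <- function(xq) if (length(g) == 1) Gy else interp(Gx, Gy, xq)
    Lat <- function(xq) if (length(l) == 1) Ly else interp(Lx, Ly, xq)

    # hull-to-hull gap, attained at a vertex of either hull
    gap_g <- Lat(Gx) - Gy  # at gcm vertices
    gap_l <- Ly - Gat(Lx)  # at lcm vertices
    if (max(gap_g) >= max(gap_l)) {
      k <- which.max(gap_g); d <- gap_g[k]
      ig <- g[k]
      seg <- max(1, findInterval(x[ig], Lx, left.open = FALSE))
      ih <- l[min(seg + 1, length(l))] # right end of covering lcm segment
    } else {
      k <- which.max(gap_l); d <- gap_l[k]
      ih <- l[k]
      seg <- max(1, findInterval(x[ih], Gx, left.open = TRUE))
      ig <- g[seg] # left end of covering gcm segment
    }
    if (d <= D) break
    if (ig <= low && ih >= high) { D <- max(D, d); break }
    # deviations of the empirical CDF from the hulls on the flanks
    dl <- if (ig > low) max(hi[low:ig] - Gat(x[low:ig])) else 0
    du <- if (ih < high) max(Lat(x[ih:high]) - lo[ih:high]) else 0
    D <- max(D, dl, du)
    low <- max(low, ig); high <- min(high, ih)
  }
  max(D / 2, 1 / (2 * n))
}

#' Dip test for bimodality of preferred directions
#'
#' Unwraps circular preferred directions to a linear axis relative to the
#' category boundary (signed difference in (-180, 180]) and applies
#' Hartigan's dip test there; the p-value comes from a Monte-Carlo null of
#' uniform samples of the same size (the standard calibration, asymptotically
#' the least favourable unimodal null).
#'
#' @param pref_dir preferred directions (deg), length >= 8.
#' @param boundary category boundary axis (deg) used as the circular cut
#'   point. The cut placement matters for circular data: cutting at the
#'   boundary puts the expected category-centre modes mid-axis.
#' @param n_boot Monte-Carlo null samples.
#' @param circular unwrap relative to the boundary first? Set FALSE for
#'   already-linear data.
#' @return list: `statistic`, `p`, `n`, `n_boot`.
#' @export
dip_test <- function(pref_dir, boundary = 0, n_boot = 1000, circular = TRUE) {
  if (length(pref_dir) < 8) stop("dip_test: need at least 8 values")
  v <- if (circular) angle_diff(pref_dir, boundary) else as.numeric(pref_dir)
  stat <- dip_stat(v)
  n <- length(v)
  null <- vapply(seq_len(n_boot), function(i) dip_stat(stats::runif(n)),
                 numeric(1))
  list(statistic = stat, p = (1 + sum(null >= stat)) / (n_boot + 1),
       n = n, n_boot = n_boot)
}
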