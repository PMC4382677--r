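#' Classical MDS of the population representation of the stimuli
#'
#' Double-centred Euclidean-distance embedding (via [stats::cmdscale()]) of
#' the stimuli-by-neurons matrix of mean firing rates: each stimulus is a
#' point in rate space and the embedding preserves pairwise distances as well
#' as two dimensions allow. The eigenvalue spectrum and the elongation of the
#' 2-D configuration (major/minor axis ratio, with the major-axis
#' orientation) are reported; a circular representation of the directions
#' gives a ratio near 1, a category-stretched representation a ratio above 1
#' with the major axis perpendicular to the boundary.
#'
#' @param mean_rates stimuli x neurons matrix (rownames = directions, deg).
#' @return list: `config` (stimuli x 2 coordinates), `eig` (eigenvalues),
#'   `axis_ratio` (sd along major / sd along minor axis), `major_angle`
#'   (orientation of the major axis in configuration space, deg in
#'   `[0, 180)`), `degenerate` (fewer than 2 positive eigenvalues),
#'   `directions`.
#' @export
classical_mds <- function(mean_rates) {
  stopifnot(nrow(mean_rates) >= 3)
  d <- stats::dist(mean_rates)
  mds <- stats::cmdscale(d, k = 2, eig = TRUE)
  degenerate <- sum(mds$eig > 1e-10 * max(abs(mds$eig))) < 2
  cfg <- mds$points
  cc <- scale(cfg, scale = FALSE)
  sv <- svd(cc)
  sds <- sv$d / sqrt(max(1, nrow(cfg) - 1))
  ratio <- if (sds[2] > 0) sds[1] / sds[2] else Inf
  ang <- atan2(sv$v[2, 1], sv$v[1, 1]) * 180 / pi
  list(config = cfg, eig = mds$eig, axis_ratio = ratio,
       major_angle = ang %% 180, degenerate = degenerate,
       directions = suppressWarnings(as.numeric(rownames(mean_rates))))
}

#' Procrustes distance between two planar configurations
#'
#' Least-squares superimposition (translation, uniform scaling, rotation and
#' optionally reflection) of configuration `X` onto `Y`; returns the residual
#' root-mean-square distance after alignment, normalized by the RMS size of
#' `Y`. Used to check that an embedding recovers a known shape up to the
#' similarity transformations MDS leaves undetermined.
#'
#' @param X,Y n x 2 matrices with corresponding rows.
#' @return normalized Procrustes RMS error (0 = identical shapes).
#' @export
procrustes_error <- function(X, Y) {
  stopifnot(all(dim(X) == dim(Y)))
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  sX <- sqrt(sum(Xc^2)); sY <- sqrt(sum(Yc^2))
  if (sX == 0 || sY == 0) return(ifelse(sX == sY, 0, 1))
  Xc <- Xc / sX; Yc <- Yc / sY
  s <- svd(crossprod(Yc, Xc))
  err2 <- 1 - sum(s$d)^2 # allows reflection
  sqrt(max(0, err2))
}
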