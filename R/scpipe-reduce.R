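#' Principal component analysis of the scaled matrix
#'
#' Deterministic (LAPACK) PCA of cells over the scaled genes.  Components
#' are orthonormal; signs are arbitrary but reproducible.
#'
#' @param scaled genes x cells scaled matrix from [scaleRegress()].
#' @param nComponents number of components to retain.
#' @return list with `scores` (cells x nComponents), `loadings`
#'   (genes x nComponents, orthonormal), `sdev` (all singular
#'   values/sqrt(n-1), for the elbow rule) and `explainedVar`
#'   (variance share of the retained components).
#' @export
pcaReduce <- function(scaled, nComponents = 50L) {
  X <- t(scaled)                     # cells x genes
  if (nComponents > min(dim(X)))
    stop("'nComponents' exceeds min(n_cells, n_genes)")
  p <- prcomp(X, center = TRUE, scale. = FALSE)
  totVar <- sum(p$sdev^2)
  idx <- seq_len(nComponents)
  list(scores = p$x[, idx, drop = FALSE],
       loadings = p$rotation[, idx, drop = FALSE],
       sdev = p$sdev,
       explainedVar = p$sdev[idx]^2 / totVar)
}

#' Choose the number of PCs at the elbow of the variance spectrum
#'
#' Operationalises "the last PC before the explained variance reaches a
#' plateau": the smallest `i` such that every subsequent drop
#' `sdev[j] - sdev[j+1]` (for `j >= i`) is below `tol` times the total,
#' floored at `floorK`.  An explicit `override` (e.g. a published PC
#' count) is honoured as given.
#'
#' @param sdev non-increasing component standard deviations.
#' @param override optional integer returned as-is.
#' @param tol drop threshold as a fraction of `sum(sdev)` (default 0.001).
#' @param floorK lower bound on the answer (default 10).
#' @return integer number of PCs.
#' @examples
#' selectPcsElbow(50 * 0.5^(1:30))          # geometric decay -> floor
#' selectPcsElbow(c(5, 4, 3, 2, rep(1, 20)), floorK = 2)
#' selectPcsElbow(seq(30, 1), override = 24)
#' @export
selectPcsElbow <- function(sdev, override = NULL, tol = 0.001,
                           floorK = 10L) {
  if (!is.null(override)) return(as.integer(override))
  if (length(sdev) < 5L)
    stop("need at least 5 components")
  if (any(diff(sdev) > 1e-8))
    stop("'sdev' must be non-increasing (sorted spectrum)")
  drops <- -diff(sdev)
  big <- which(drops >= tol * sum(sdev))
  k <- if (length(big)) max(big) + 1L else 1L
  as.integer(min(max(k, floorK), length(sdev)))
}
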