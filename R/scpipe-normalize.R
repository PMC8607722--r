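.countsMatrix <- function(x) {
  if (methods::is(x, "SummarizedExperiment"))
    x <- SummarizedExperiment::assay(x, "counts")
  as.matrix(x)
}

#' Counts-per-million log2 normalisation
#'
#' `log2(1 + 1e6 * count / cell_total)` per cell.  Centring and scaling
#' are deferred to [scaleRegress()].
#'
#' @param counts genes x cells integer matrix, or a
#'   SingleCellExperiment/SummarizedExperiment with a `counts` assay.
#' @return if the input is an SCE, the same object with a `logcpm` assay
#'   added; otherwise the normalised genes x cells matrix.
#' @examples
#' m <- matrix(c(1, 0, 3, 2, 2, 0), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("c1", "c2")))
#' normalizeCpmLog(m)
#' @export
normalizeCpmLog <- function(counts) {
  mat <- .countsMatrix(counts)
  totals <- colSums(mat)
  zero <- which(totals == 0)
  if (length(zero))
    stop("cell(s) with zero total counts: ",
         paste(colnames(mat)[zero], collapse = ", "))
  norm <- log2(1 + sweep(mat, 2, totals, "/") * 1e6)
  if (methods::is(counts, "SummarizedExperiment")) {
    SummarizedExperiment::assay(counts, "logcpm") <- norm
    counts
  } else norm
}

.normMatrix <- function(x) {
  if (methods::is(x, "SummarizedExperiment"))
    x <- SummarizedExperiment::assay(x, "logcpm")
  as.matrix(x)
}

.rowVars <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

#' Select highly variable genes by standardised variance
#'
#' Genes are ranked by the variance of their clipped z-scores under a
#' mean-variance trend: a loess fit of log10 variance on log10 mean gives
#' each gene an expected standard deviation; values are standardised with
#' it, clipped at `sqrt(n_cells)`, and the variance of the clipped
#' z-scores is the ranking statistic.
#'
#' @param norm genes x cells normalised matrix (or SCE with `logcpm`).
#' @param nFeatures number of genes to return (default 2000).
#' @param span loess span of the mean-variance trend.
#' @return character vector of gene names, ordered by decreasing
#'   standardised variance.
#' @export
selectHvg <- function(norm, nFeatures = 2000L, span = 0.5) {
  mat <- .normMatrix(norm)
  if (nFeatures > nrow(mat))
    stop("'nFeatures' exceeds the number of genes")
  means <- rowMeans(mat)
  vars <- .rowVars(mat)
  if (all(vars == 0))
    stop("constant matrix: no variable genes")
  use <- vars > 0 & means > 0
  fit <- loess(log10(vars[use]) ~ log10(means[use]), span = span,
               degree = 2)
  sdExp <- rep(NA_real_, nrow(mat))
  sdExp[use] <- sqrt(pmax(10^predict(fit), .Machine$double.eps))
  clipMax <- sqrt(ncol(mat))
  stdVar <- vapply(seq_len(nrow(mat)), function(i) {
    if (!use[i]) return(0)
    z <- (mat[i, ] - means[i]) / sdExp[i]
    z <- pmin(pmax(z, -clipMax), clipMax)
    var(z)
  }, numeric(1))
  names(stdVar) <- rownames(mat)
  names(sort(stdVar, decreasing = TRUE))[seq_len(nFeatures)]
}

#' Regress out covariates, then z-score and clip
#'
#' For each gene (restricted to `hvg` if given): least-squares residuals
#' of the normalised expression on the per-cell covariates (with
#' intercept), divided by the residual standard deviation and clipped at
#' +/- `clip`.  Covariates with zero variance are skipped with a warning.
#'
#' @param norm genes x cells normalised matrix (or SCE with `logcpm` and
#'   covariates in `colData`).
#' @param hvg gene names to keep (default: all genes).
#' @param covariates character; covariate names, looked up in `cellMeta`
#'   (default `"percent_mito"`).
#' @param cellMeta data.frame of per-cell covariates (taken from
#'   `colData` when `norm` is an SCE).
#' @param clip clipping bound for the scaled values (default 10).
#' @return genes x cells matrix of scaled residuals.
#' @export
scaleRegress <- function(norm, hvg = NULL, covariates = "percent_mito",
                         cellMeta = NULL, clip = 10) {
  if (methods::is(norm, "SummarizedExperiment") && is.null(cellMeta))
    cellMeta <- as.data.frame(SummarizedExperiment::colData(norm))
  mat <- .normMatrix(norm)
  if (!is.null(hvg)) {
    missing <- setdiff(hvg, rownames(mat))
    if (length(missing))
      stop("hvg gene(s) absent from the matrix: ",
           paste(head(missing, 5), collapse = ", "))
    mat <- mat[hvg, , drop = FALSE]
  }
  X <- matrix(1, nrow = ncol(mat), ncol = 1)
  for (cv in covariates) {
    if (is.null(cellMeta) || !cv %in% names(cellMeta))
      stop(sprintf("covariate '%s' not found in cell metadata", cv))
    v <- cellMeta[[cv]]
    if (var(v) == 0) {
      warning(sprintf("covariate '%s' has zero variance; skipped", cv))
      next
    }
    X <- cbind(X, v)
  }
  qrX <- qr(X)
  Q <- qr.Q(qrX)
  ## residuals for all genes at once: R = M - (M Q) Q'
  Mt <- t(mat)                      # cells x genes
  resid <- Mt - Q %*% (t(Q) %*% Mt)
  sds <- sqrt(colSums(resid^2) / (nrow(resid) - 1))
  sds[sds < 1e-8] <- 1     # numerically zero residual: leave unscaled
  scaled <- sweep(resid, 2, sds, "/")
  scaled <- pmin(pmax(scaled, -clip), clip)
  t(scaled)
}
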