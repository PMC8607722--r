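#' Stage/region association of variant genes with expression
#'
#' For every (region, period) cell of a spatiotemporal grid, builds the
#' 2x2 table over `geneSet` crossing (expression at or above the
#' within-cell quantile) x (gene carries a variant), and reports the
#' hypergeometric enrichment p and sample odds ratio.  A cell whose
#' expressions are all equal is flagged degenerate (OR NA, p 1).
#'
#' @param stExpr a SummarizedExperiment grid from
#'   [generateSpatiotemporal()] / [readSpatioTsv()] (assay `rpkm`,
#'   colData `region`, `period`).
#' @param variantGenes character vector (or [GeneSet-class]) of genes
#'   harbouring variants.
#' @param geneSet genes to analyse (default: all grid genes); must be a
#'   subset of the grid.
#' @param exprQuantile binarisation quantile within each grid cell
#'   (default 0.5, the median).
#' @return data.frame with one row per grid cell: `region`, `period`,
#'   `n_genes`, `n_high`, `n_variant`, `overlap`, `odds_ratio`, `p`,
#'   `degenerate`.
#' @export
stageRegionAssociation <- function(stExpr, variantGenes, geneSet = NULL,
                                   exprQuantile = 0.5) {
  mat <- SummarizedExperiment::assay(stExpr, "rpkm")
  cd <- SummarizedExperiment::colData(stExpr)
  if (is(variantGenes, "GeneSet")) variantGenes <- geneIds(variantGenes)
  if (is.null(geneSet)) geneSet <- rownames(mat)
  missing <- setdiff(geneSet, rownames(mat))
  if (length(missing))
    stop("gene set member(s) absent from the grid: ",
         paste(head(missing, 5), collapse = ", "))
  mat <- mat[geneSet, , drop = FALSE]
  variant <- geneSet %in% variantGenes
  rows <- lapply(seq_len(ncol(mat)), function(j) {
    e <- mat[, j]
    if (length(unique(e)) == 1L)
      return(data.frame(region = cd$region[j], period = cd$period[j],
                        n_genes = length(e), n_high = NA_integer_,
                        n_variant = sum(variant), overlap = NA_integer_,
                        odds_ratio = NA_real_, p = 1, degenerate = TRUE,
                        stringsAsFactors = FALSE))
    high <- e >= quantile(e, exprQuantile)
    n11 <- sum(high & variant); n10 <- sum(high & !variant)
    n01 <- sum(!high & variant); n00 <- sum(!high & !variant)
    p <- phyper(n11 - 1, sum(variant), sum(!variant), sum(high),
                lower.tail = FALSE)
    data.frame(region = cd$region[j], period = cd$period[j],
               n_genes = length(e), n_high = sum(high),
               n_variant = sum(variant), overlap = n11,
               odds_ratio = .sampleOR(n11, n10, n01, n00), p = p,
               degenerate = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Detection filter for a sorted-cell reference
#'
#' Retains genes detected in more than `minFraction` of cells (per the
#' per-gene detection fraction in `rowData`); when no detection data is
#' available, retains genes with nonzero expression in every cell type.
#'
#' @param sortedExpr SummarizedExperiment from
#'   [generateSortedCellReference()] / [readSortedTsv()].
#' @param minFraction detection threshold (default 0.75).
#' @return the filtered SummarizedExperiment.
#' @export
detectionFilter <- function(sortedExpr, minFraction = 0.75) {
  rd <- SummarizedExperiment::rowData(sortedExpr)
  if ("detection" %in% names(rd)) {
    keep <- rd$detection > minFraction
  } else {
    mat <- SummarizedExperiment::assay(sortedExpr, 1)
    keep <- rowSums(mat == 0) == 0
  }
  sortedExpr[keep, ]
}

#' Fold change versus neurons in a sorted-cell reference
#'
#' `FC(gene, type) = (expr + pseudocount) / (expr_neurons + pseudocount)`
#' for every non-neuronal cell type, plus the top-`k` genes by maximal
#' non-neuronal fold change (the "top 10 most fold change genes" view,
#' by default).
#'
#' @param sortedExpr SummarizedExperiment with a `neurons` column.
#' @param geneSet genes to analyse (default: all).
#' @param pseudocount added to both sides of the ratio (default 0.01).
#' @param k top genes to report (default 10).
#' @return list with `fc` (genes x non-neuronal types), `meanExpr`
#'   (genes x all types) and `top` (character vector of the top-k
#'   genes).
#' @export
foldChangeVsNeurons <- function(sortedExpr, geneSet = NULL,
                                pseudocount = 0.01, k = 10L) {
  mat <- SummarizedExperiment::assay(sortedExpr, 1)
  if (!"neurons" %in% colnames(mat))
    stop("'neurons' column missing: no fold-change reference")
  if (!is.null(geneSet)) {
    if (is(geneSet, "GeneSet")) geneSet <- geneIds(geneSet)
    mat <- mat[intersect(geneSet, rownames(mat)), , drop = FALSE]
  }
  others <- setdiff(colnames(mat), "neurons")
  fc <- (mat[, others, drop = FALSE] + pseudocount) /
    (mat[, "neurons"] + pseudocount)
  maxFc <- apply(fc, 1, max)
  top <- names(sort(maxFc, decreasing = TRUE))[seq_len(min(k, nrow(mat)))]
  list(fc = fc, meanExpr = mat, top = top)
}

#' Compare two value sets (t test or Fisher association)
#'
#' Dispatcher reused by the replication analyses: `"ttest"` delegates to
#' the Welch test of [deTtest()] on two numeric vectors (mean expression
#' or fold changes); `"fisher"` treats the two logical vectors as a
#' binarised association and returns the hypergeometric enrichment p of
#' their joint TRUEs.
#'
#' @param a,b numeric vectors (`"ttest"`) or equal-length logical
#'   vectors (`"fisher"`).
#' @param method `"ttest"` or `"fisher"`.
#' @return p-value.
#' @export
compareSets <- function(a, b, method = c("ttest", "fisher")) {
  method <- match.arg(method)
  if (method == "ttest") return(deTtest(a, b))
  if (length(a) != length(b))
    stop("logical vectors must have equal length for the association test")
  idx <- as.character(seq_along(a))
  fisherOverlap(idx[a], idx[b], idx)$p
}
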