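#' Mean marker expression per cluster and cell type
#'
#' Average normalised expression of each cell type's marker genes over
#' each cluster's cells.  Markers absent from the matrix are dropped with
#' a message.
#'
#' @param norm genes x cells normalised matrix (or SCE with `logcpm`).
#' @param labeling a [ClusterLabeling-class] (or named label vector).
#' @param catalog named list: cell type -> marker gene vector (or
#'   [GeneSet-class] objects).
#' @return clusters x cell-types numeric matrix.
#' @export
meanMarkerExpression <- function(norm, labeling, catalog) {
  mat <- .normMatrix(norm)
  labels <- if (is(labeling, "ClusterLabeling")) clusterLabels(labeling)
            else labeling
  labels <- labels[colnames(mat)]
  catalog <- lapply(catalog, function(s)
    if (is(s, "GeneSet")) geneIds(s) else s)
  present <- lapply(catalog, intersect, rownames(mat))
  nDropped <- sum(lengths(catalog)) - sum(lengths(present))
  if (nDropped > 0)
    message(sprintf("%d marker gene(s) absent from the matrix; dropped",
                    nDropped))
  clusters <- sort(unique(labels))
  out <- vapply(names(present), function(ct) {
    mk <- present[[ct]]
    vapply(clusters, function(cl) {
      if (!length(mk)) return(NA_real_)
      mean(mat[mk, labels == cl, drop = FALSE])
    }, numeric(1))
  }, numeric(length(clusters)))
  out <- matrix(out, nrow = length(clusters),
                dimnames = list(as.character(clusters), names(present)))
  out
}

#' Composition of the top differentially expressed genes by marker type
#'
#' For each cluster, the fraction of its top-`n` consensus DEGs (ranked
#' by decreasing fold change) that fall in each cell type's marker set;
#' the remainder is reported as `others`.  Clusters with fewer than `n`
#' DEGs use all of them (`n_effective` records how many).
#'
#' @param consensus named list of per-cluster DEG data.frames from
#'   [consensusDE()] (ranked by decreasing `log2_fc`).
#' @param catalog named list: cell type -> marker genes.
#' @param n top genes considered (default 20; 10 is used for the
#'   validation-style analyses).
#' @return list with `composition` (clusters x (types + others) matrix of
#'   fractions) and `n_effective` (named integer).
#' @export
topDegComposition <- function(consensus, catalog, n = 20L) {
  catalog <- lapply(catalog, function(s)
    if (is(s, "GeneSet")) geneIds(s) else s)
  types <- names(catalog)
  comp <- t(vapply(names(consensus), function(cl) {
    genes <- head(consensus[[cl]]$gene, n)
    fr <- vapply(types, function(ct)
      mean(genes %in% catalog[[ct]]), numeric(1))
    c(fr, others = max(0, 1 - sum(fr)))
  }, numeric(length(types) + 1L)))
  nEff <- vapply(consensus, function(d) min(n, nrow(d)), integer(1))
  list(composition = comp, n_effective = nEff)
}

#' Assign cell-type identity to clusters
#'
#' Conjunction rule operationalising marker-evidence annotation: a
#' cluster is called a cell type when that type (i) has the largest
#' top-DEG composition fraction, at least `tau`, and (ii) also maximises
#' the mean marker expression; any shortfall, tie or conflict between
#' the two lines of evidence yields `"unassigned"` (mirroring clusters
#' that cannot be annotated from the available markers).
#'
#' @param composition clusters x types fraction matrix (the `others`
#'   column, if present, is ignored for the argmax).
#' @param meanMarkerExpr clusters x types matrix from
#'   [meanMarkerExpression()].
#' @param tau minimum composition fraction (default 0.25).
#' @return data.frame: `cluster`, `call`, `top_type`, `top_fraction`,
#'   `expr_type`, `tie` (logical).
#' @export
assignCellType <- function(composition, meanMarkerExpr, tau = 0.25) {
  types <- setdiff(colnames(composition), "others")
  clusters <- rownames(composition)
  rows <- lapply(clusters, function(cl) {
    fr <- composition[cl, types]
    ex <- meanMarkerExpr[cl, types]
    topFr <- max(fr)
    tie <- sum(fr == topFr) > 1L
    topType <- types[which.max(fr)]
    exprType <- types[which.max(ex)]
    call <- if (!tie && topFr >= tau && identical(topType, exprType))
      topType else "unassigned"
    data.frame(cluster = cl, call = call, top_type = topType,
               top_fraction = unname(topFr), expr_type = exprType,
               tie = tie, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Annotate clusters end-to-end
#'
#' Convenience wrapper: [meanMarkerExpression()] +
#' [topDegComposition()] + [assignCellType()].
#'
#' @param norm normalised matrix or SCE with `logcpm`.
#' @param labeling a [ClusterLabeling-class].
#' @param consensus per-cluster DEG lists from [consensusDE()].
#' @param catalog marker catalogue (named list).
#' @param n top DEGs considered (default 20).
#' @param tau composition threshold (default 0.25).
#' @return the [assignCellType()] data.frame with an extra
#'   `n_effective` column.
#' @export
annotateClusters <- function(norm, labeling, consensus, catalog, n = 20L,
                             tau = 0.25) {
  expr <- meanMarkerExpression(norm, labeling, catalog)
  comp <- topDegComposition(consensus, catalog, n = n)
  ## align on the clusters that have DEGs
  common <- intersect(rownames(comp$composition), rownames(expr))
  calls <- assignCellType(comp$composition[common, , drop = FALSE],
                          expr[common, , drop = FALSE], tau = tau)
  calls$n_effective <- comp$n_effective[common]
  calls
}
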