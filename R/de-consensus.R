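.deTestNames <- c("wilcox", "t", "bimod", "hurdle")

#' One-vs-rest differential expression under four tests
#'
#' For every cluster, each candidate gene is tested in-cluster versus all
#' remaining cells with the Wilcoxon rank-sum, Welch t, bimodal
#' likelihood-ratio and hurdle tests on the log2 CPM values.  The
#' candidate prefilter keeps a gene when it is detected in at least
#' `minPct` of the in-cluster cells and its |log2 fold change| (ratio of
#' mean CPM with pseudocount 1) is at least `minLfc`; disable it with
#' `prefilter = FALSE`.  Per-test Bonferroni adjustment uses the number
#' of genes actually tested in that cluster.
#'
#' @param sce SingleCellExperiment with `counts` (and `logcpm`, computed
#'   when absent).
#' @param labeling a [ClusterLabeling-class] covering the cells.
#' @param minPct detection prefilter (default 0.1).
#' @param minLfc fold-change prefilter on |log2 FC| (default 0.25).
#' @param prefilter apply the candidate filter (default TRUE).
#' @return data.frame with one row per (cluster, tested gene): `gene`,
#'   `cluster`, `log2_fc`, `pct_in`, `pct_out`, `p_<test>` and
#'   `p_adj_<test>` for the four tests.
#' @seealso [consensusDE()] for the all-four-significant intersection.
#' @export
runConsensusDE <- function(sce, labeling, minPct = 0.1, minLfc = 0.25,
                           prefilter = TRUE) {
  if (!"logcpm" %in% SummarizedExperiment::assayNames(sce))
    sce <- normalizeCpmLog(sce)
  counts <- SummarizedExperiment::assay(sce, "counts")
  norm <- SummarizedExperiment::assay(sce, "logcpm")
  labels <- clusterLabels(labeling)
  if (!all(colnames(sce) %in% names(labels)))
    stop("labeling does not cover all cells")
  labels <- labels[colnames(sce)]
  cpm <- 2^norm - 1
  detected <- counts > 0

  res <- lapply(sort(unique(labels)), function(cl) {
    inCells <- labels == cl
    pctIn <- rowMeans(detected[, inCells, drop = FALSE])
    pctOut <- rowMeans(detected[, !inCells, drop = FALSE])
    meanIn <- rowMeans(cpm[, inCells, drop = FALSE])
    meanOut <- rowMeans(cpm[, !inCells, drop = FALSE])
    lfc <- log2((meanIn + 1) / (meanOut + 1))
    cand <- if (prefilter) which(pctIn >= minPct & abs(lfc) >= minLfc)
            else seq_len(nrow(norm))
    if (!length(cand)) return(NULL)
    pv <- t(vapply(cand, function(g) {
      xin <- norm[g, inCells]
      xout <- norm[g, !inCells]
      c(wilcox = deWilcoxon(xin, xout),
        t = deTtest(xin, xout),
        bimod = deBimod(xin, xout),
        hurdle = as.numeric(deHurdle(xin, xout)))
    }, numeric(4)))
    out <- data.frame(gene = rownames(norm)[cand], cluster = cl,
                      log2_fc = lfc[cand], pct_in = pctIn[cand],
                      pct_out = pctOut[cand], stringsAsFactors = FALSE)
    for (tn in .deTestNames) {
      out[[paste0("p_", tn)]] <- pv[, tn]
      out[[paste0("p_adj_", tn)]] <- adjustP(pv[, tn], "bonferroni",
                                             m = length(cand))
    }
    out
  })
  do.call(rbind, res)
}

#' Consensus differentially expressed genes
#'
#' A gene is a consensus DEG for a cluster when its adjusted p-value is
#' below `threshold` in all four tests; per cluster the genes are
#' ordered by decreasing log2 fold change.
#'
#' @param deTable output of [runConsensusDE()].
#' @param threshold adjusted-p cutoff (default 0.001).
#' @return named list (one element per cluster) of data.frames, each the
#'   significant rows of `deTable` ordered by decreasing `log2_fc`.
#' @export
consensusDE <- function(deTable, threshold = 0.001) {
  need <- paste0("p_adj_", .deTestNames)
  missing <- setdiff(need, names(deTable))
  if (length(missing))
    stop("missing test column(s): ", paste(missing, collapse = ", "))
  keep <- Reduce(`&`, lapply(need, function(cn) deTable[[cn]] < threshold))
  sig <- deTable[keep, , drop = FALSE]
  out <- split(sig, sig$cluster)
  lapply(out, function(d) d[order(d$log2_fc, decreasing = TRUE), ,
                            drop = FALSE])
}
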