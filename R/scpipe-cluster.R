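#' Shared-nearest-neighbour graph on PCA scores
#'
#' Finds the `k` nearest neighbours of every cell in PC space, then
#' weights each candidate edge by the shared-neighbour Jaccard index
#' |shared| / |union| of the two cells' neighbour sets (each set includes
#' the cell itself).  Edges with weight below `prune` (default 1/15) are
#' removed; a cell left isolated by pruning is reattached to its nearest
#' neighbour at the pruning weight so every node keeps at least one edge.
#'
#' @param scores cells x PCs matrix.
#' @param k neighbours per cell (default 20).
#' @param prune minimum SNN weight kept (default 1/15).
#' @return an undirected weighted [igraph::igraph] graph with one vertex
#'   per cell (named by row names).
#' @export
knnGraph <- function(scores, k = 20L, prune = 1 / 15) {
  n <- nrow(scores)
  if (k >= n) stop("'k' must be smaller than the number of cells")
  ids <- rownames(scores)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  nn <- FNN::get.knn(scores, k = k)$nn.index
  nbr <- lapply(seq_len(n), function(i) c(i, nn[i, ]))

  ## candidate edges: every (i, j) with j a kNN of i
  ei <- rep(seq_len(n), each = k)
  ej <- as.vector(t(nn))
  keep <- ei < ej
  pairs <- unique(rbind(cbind(ei[keep], ej[keep]),
                        cbind(ej[!keep], ei[!keep])))
  w <- vapply(seq_len(nrow(pairs)), function(r) {
    a <- nbr[[pairs[r, 1]]]
    b <- nbr[[pairs[r, 2]]]
    s <- length(intersect(a, b))
    s / (2 * (k + 1) - s)
  }, numeric(1))
  ok <- w >= prune
  pairs <- pairs[ok, , drop = FALSE]
  w <- w[ok]

  ## reattach isolated cells to their nearest neighbour
  touched <- unique(as.vector(pairs))
  lonely <- setdiff(seq_len(n), touched)
  if (length(lonely)) {
    extra <- cbind(lonely, nn[lonely, 1])
    pairs <- rbind(pairs, extra)
    w <- c(w, rep(prune, length(lonely)))
  }

  g <- igraph::graph_from_edgelist(
    matrix(ids[pairs], ncol = 2), directed = FALSE)
  g <- igraph::add_vertices(g, length(setdiff(ids, igraph::V(g)$name)),
                            name = setdiff(ids, igraph::V(g)$name))
  igraph::E(g)$weight <- w
  g <- igraph::simplify(g, edge.attr.comb = "max")
  ## fix vertex order to the input order for determinism
  igraph::permute(g, match(igraph::V(g)$name, ids))
}

#' Leiden clustering of the SNN graph
#'
#' Modularity-optimising Leiden community detection at the given
#' resolution.  Cluster ids are 0-based and relabelled by decreasing
#' cluster size (cluster 0 is the largest).
#'
#' @param graph an SNN graph from [knnGraph()].
#' @param resolution modularity resolution parameter (the published runs
#'   used 0.8, 0.5, 0.6 for the three cortical regions).
#' @param seed integer seed for the partition refinement.
#' @param nIterations Leiden iterations (default 10).
#' @param params extra fields recorded in the labeling's `params`.
#' @return a [ClusterLabeling-class].
#' @export
clusterCells <- function(graph, resolution = 0.8, seed = 1L,
                         nIterations = 10L, params = list()) {
  if (igraph::vcount(graph) == 0L) stop("empty graph")
  set.seed(seed)
  cl <- igraph::cluster_leiden(graph, objective_function = "modularity",
                               resolution = resolution,
                               weights = igraph::E(graph)$weight,
                               n_iterations = nIterations)
  memb <- igraph::membership(cl)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes) - 1L, names(sizes))
  labels <- unname(relabel[as.character(memb)])
  names(labels) <- igraph::V(graph)$name
  storage.mode(labels) <- "integer"
  newSizes <- table(labels)
  new("ClusterLabeling",
      labels = labels,
      params = utils::modifyList(
        list(resolution = resolution, seed = as.integer(seed)), params),
      sizes = setNames(as.integer(newSizes), names(newSizes)))
}

#' tSNE embedding of the PCA scores
#'
#' Two-dimensional t-distributed stochastic neighbour embedding for
#' visualisation only; nothing downstream depends on it.
#'
#' @param scores cells x PCs matrix.
#' @param perplexity tSNE perplexity (default 30).
#' @param seed integer seed.
#' @return cells x 2 coordinate matrix.
#' @export
embedTsne <- function(scores, perplexity = 30, seed = 1L) {
  n <- nrow(scores)
  if (perplexity >= (n - 1) / 3)
    stop("perplexity too large for the number of cells")
  set.seed(seed)
  fit <- Rtsne::Rtsne(scores, dims = 2, perplexity = perplexity,
                      pca = FALSE, check_duplicates = FALSE)
  out <- fit$Y
  rownames(out) <- rownames(scores)
  colnames(out) <- c("tSNE1", "tSNE2")
  out
}

#' Run the full clustering pipeline on a count matrix
#'
#' Normalise (CPM/log2), select highly variable genes, regress out the
#' mitochondrial fraction and scale, run PCA, pick the PC count by the
#' elbow rule (or an override), build the SNN graph and cluster with
#' Leiden.  Identical inputs and seed give identical labels.
#'
#' @param sce a SingleCellExperiment with a `counts` assay and
#'   `percent_mito` in `colData`.
#' @param resolution Leiden resolution (default 0.8).
#' @param nPcs PC count override; `NULL` uses the elbow rule.
#' @param knnK neighbours for the SNN graph (default 20).
#' @param nHvg variable genes (default 2000, capped at the gene count).
#' @param covariates covariates to regress out.
#' @param seed integer seed.
#' @param tsne also compute the tSNE embedding (default FALSE).
#' @return list with `labeling` (a [ClusterLabeling-class]), `scores`,
#'   `sdev`, `nPcs`, `hvg`, `graph`, `sce` (with `logcpm` added) and
#'   optionally `tsne`.
#' @export
runClusterPipeline <- function(sce, resolution = 0.8, nPcs = NULL,
                               knnK = 20L, nHvg = 2000L,
                               covariates = "percent_mito", seed = 1L,
                               tsne = FALSE) {
  sce <- normalizeCpmLog(sce)
  nHvg <- min(nHvg, nrow(sce))
  hvg <- selectHvg(sce, nFeatures = nHvg)
  scaled <- scaleRegress(sce, hvg = hvg, covariates = covariates)
  maxPc <- min(50L, min(dim(scaled)) - 1L)
  pca <- pcaReduce(scaled, nComponents = maxPc)
  k <- selectPcsElbow(pca$sdev[seq_len(maxPc)], override = nPcs)
  scores <- pca$scores[, seq_len(k), drop = FALSE]
  graph <- knnGraph(scores, k = knnK)
  labeling <- clusterCells(graph, resolution = resolution, seed = seed,
                           params = list(n_pcs = k, knn_k = as.integer(knnK)))
  out <- list(labeling = labeling, scores = scores, sdev = pca$sdev,
              nPcs = k, hvg = hvg, graph = graph, sce = sce)
  if (tsne)
    out$tsne <- embedTsne(scores,
                          perplexity = min(30, (nrow(scores) - 2) / 3 - 1),
                          seed = seed)
  out
}
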