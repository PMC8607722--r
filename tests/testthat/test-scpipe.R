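test_that("CPM/log2 normalisation matches the closed form", {
  m <- matrix(c(1, 999999, 0, 2, 2, 6), nrow = 3,
              dimnames = list(paste0("g", 1:3), c("c1", "c2")))
  n <- normalizeCpmLog(m)
  # cell total 1e6, count 1 -> log2(2) = 1
  expect_equal(n["g1", "c1"], 1)
  # 3x3 toy matrix against hand computation
  toy <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), nrow = 3)
  hand <- log2(1 + sweep(toy, 2, colSums(toy), "/") * 1e6)
  expect_equal(normalizeCpmLog(toy), hand, tolerance = 1e-12)
  # doubling a cell's counts leaves its CPM unchanged
  expect_equal(normalizeCpmLog(toy)[, 1], normalizeCpmLog(toy * 2)[, 1])
  # all-zero cells are named in the error
  bad <- cbind(c1 = c(1, 2), dead = c(0, 0))
  expect_error(normalizeCpmLog(bad), "dead")
})

test_that("HVG selection ranks planted markers on top", {
  syn <- smallStudy(seed = 51)
  sce <- normalizeCpmLog(syn$sce)
  hvg <- selectHvg(sce, nFeatures = 100L)
  markers <- unlist(syn$truth@markerCatalog)
  expect_gte(mean(markers %in% hvg), 0.9)
  # n = n_genes returns every gene; larger n errors
  expect_setequal(selectHvg(sce, nFeatures = nrow(sce)), rownames(sce))
  expect_error(selectHvg(sce, nFeatures = nrow(sce) + 1L), "exceeds")
  expect_error(selectHvg(matrix(1, 30, 10), nFeatures = 5), "constant")
})

test_that("covariate regression matches the normal-equations oracle", {
  set.seed(61)
  norm <- matrix(rnorm(50 * 20), nrow = 20,
                 dimnames = list(paste0("g", 1:20), paste0("c", 1:50)))
  meta <- data.frame(percent_mito = runif(50, 1, 10))
  scaled <- scaleRegress(norm, cellMeta = meta)
  X <- cbind(1, meta$percent_mito)
  for (g in c(1, 7, 20)) {
    r <- oracleLsResiduals(norm[g, ], X)
    expect_equal(unname(scaled[g, ]), unname(r / sd(r)), tolerance = 1e-8)
  }
  # expression exactly linear in the covariate leaves ~zero residuals
  lin <- matrix(rep(2 * meta$percent_mito + 1, 3), nrow = 3, byrow = TRUE)
  rownames(lin) <- paste0("g", 1:3)
  colnames(lin) <- paste0("c", 1:50)
  expect_lt(max(abs(scaleRegress(lin, cellMeta = meta))), 1e-6)
  # orthogonal covariate: residuals equal centred values (up to scaling)
  orth <- matrix(rnorm(50), nrow = 1,
                 dimnames = list("g1", paste0("c", 1:50)))
  constMeta <- data.frame(percent_mito = rep(5, 50))
  expect_warning(s0 <- scaleRegress(orth, cellMeta = constMeta),
                 "zero variance")
  centred <- orth[1, ] - mean(orth[1, ])
  expect_equal(unname(s0[1, ]), unname(centred / sd(centred)),
               tolerance = 1e-10)
})

test_that("PCA components are orthonormal and match the eigen oracle", {
  set.seed(62)
  scaled <- matrix(rnorm(40 * 30), nrow = 30)  # 30 genes x 40 cells
  rownames(scaled) <- paste0("g", 1:30)
  colnames(scaled) <- paste0("c", 1:40)
  p <- pcaReduce(scaled, nComponents = 10L)
  I <- crossprod(p$loadings)
  expect_lt(max(abs(I - diag(10))), 1e-8)
  # full-rank variance conservation
  pf <- pcaReduce(scaled, nComponents = 30L)
  X <- t(scaled)
  expect_equal(sum(pf$sdev^2), sum(apply(X, 2, var)), tolerance = 1e-10)
  # scores reproduce the covariance eigendecomposition
  C <- cov(X)
  ev <- eigen(C, symmetric = TRUE)
  expect_equal(unname(p$sdev[1:5]^2), ev$values[1:5], tolerance = 1e-8)
  Xc <- sweep(X, 2, colMeans(X))
  for (j in 1:3) {
    s <- drop(Xc %*% ev$vectors[, j])
    expect_equal(abs(cor(s, p$scores[, j])), 1, tolerance = 1e-8)
  }
  expect_error(pcaReduce(scaled, nComponents = 60L), "exceeds")
})

test_that("the elbow rule honours overrides, floors and plateaus", {
  expect_identical(selectPcsElbow(seq(30, 1), override = 24), 24L)
  # strictly geometric decay: drops fall below tolerance early -> floor
  expect_identical(selectPcsElbow(50 * 0.5^(1:30)), 10L)
  # spectrum flat from component 12 onwards
  sdev <- c(seq(30, 8, length.out = 12), rep(8, 20))
  expect_identical(selectPcsElbow(sdev), 12L)
  expect_error(selectPcsElbow(c(1, 2, 3, 4, 5)), "non-increasing")
  expect_error(selectPcsElbow(c(3, 2, 1)), "5 components")
})

test_that("the SNN graph separates distant blobs and finds true neighbours", {
  set.seed(63)
  blobA <- matrix(rnorm(30 * 2), ncol = 2)
  blobB <- matrix(rnorm(30 * 2), ncol = 2) + 100
  scores <- rbind(blobA, blobB)
  rownames(scores) <- sprintf("c%02d", 1:60)
  g <- knnGraph(scores, k = 10)
  ends <- igraph::as_edgelist(g)
  side <- function(id) as.integer(sub("c", "", id)) <= 30
  expect_true(all(side(ends[, 1]) == side(ends[, 2])))
  expect_gte(min(igraph::degree(g)), 1)
  # k = 1 on collinear points: edges match brute-force nearest neighbours
  x <- cbind(c(0, 1, 2.1, 3.3, 4.6, 6), 0)
  rownames(x) <- paste0("p", 1:6)
  g1 <- knnGraph(x, k = 1)
  d <- as.matrix(dist(x)); diag(d) <- Inf
  nnBrute <- apply(d, 1, which.min)
  el <- igraph::as_edgelist(g1)
  for (i in 1:6) {
    partner <- rownames(x)[nnBrute[i]]
    hit <- (el[, 1] == rownames(x)[i] & el[, 2] == partner) |
           (el[, 2] == rownames(x)[i] & el[, 1] == partner)
    expect_true(any(hit))
  }
  expect_error(knnGraph(scores, k = 60), "smaller")
})

test_that("Leiden clustering recovers planted types and is deterministic", {
  syn <- smallStudy(seed = 52)
  pipe <- runClusterPipeline(syn$sce, resolution = 0.8, seed = 1)
  labels <- clusterLabels(pipe$labeling)
  truth <- syn$truth@cellLabels[names(labels)]
  expect_gte(ari(labels, truth), 0.95)
  # coverage + size bookkeeping
  expect_identical(length(labels), ncol(syn$sce))
  expect_identical(sum(clusterSizes(pipe$labeling)), length(labels))
  expect_gte(min(clusterSizes(pipe$labeling)), 1L)
  # labels 0-based, ordered by decreasing size
  sizes <- clusterSizes(pipe$labeling)
  expect_identical(names(sizes)[1], "0")
  expect_true(all(diff(unname(sizes)) <= 0))
  # determinism
  pipe2 <- runClusterPipeline(syn$sce, resolution = 0.8, seed = 1)
  expect_identical(labels, clusterLabels(pipe2$labeling))
  # params recorded
  expect_equal(clusterParams(pipe$labeling)$resolution, 0.8)
  expect_true(all(c("n_pcs", "knn_k", "seed") %in%
                  names(clusterParams(pipe$labeling))))
})

test_that("resolution near zero collapses to a single cluster", {
  syn <- smallStudy(seed = 53)
  pipe <- runClusterPipeline(syn$sce, resolution = 1e-6, seed = 1)
  expect_identical(length(clusterSizes(pipe$labeling)), 1L)
})

test_that("tSNE returns finite 2-D coordinates and respects its bounds", {
  set.seed(64)
  scores <- matrix(rnorm(80 * 5), ncol = 5)
  rownames(scores) <- sprintf("c%02d", 1:80)
  emb <- embedTsne(scores, perplexity = 10, seed = 2)
  expect_identical(dim(emb), c(80L, 2L))
  expect_true(all(is.finite(emb)))
  # duplicated rows land next to each other
  dup <- rbind(scores, scores[1, , drop = FALSE])
  rownames(dup) <- c(rownames(scores), "dup1")
  e2 <- embedTsne(dup, perplexity = 10, seed = 2)
  d <- as.matrix(dist(e2))["c01", ]
  expect_true("dup1" %in% names(sort(d))[2:4])
  expect_error(embedTsne(scores, perplexity = 30), "perplexity")
})
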