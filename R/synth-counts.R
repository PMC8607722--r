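#' Generate a synthetic cell-by-gene count matrix with planted cell types
#'
#' Counts follow a negative-binomial model: gene baseline means are drawn
#' log-normal, each planted marker's mean is multiplied by
#' `2^markerLog2Effect` in its home type, per-cell relative abundances are
#' renormalised and scaled by a uniform library size, and
#' `rnbinom(mu, size = 1/dispersion)` draws the counts.  A per-cell
#' mitochondrial-read percentage correlated with library size is simulated
#' as a covariate so the regression step of the clustering pipeline has
#' signal to remove.
#'
#' The returned [SingleCellExperiment::SingleCellExperiment] carries the
#' integer `counts` assay, `colData` columns `donor`, `region` and
#' `percent_mito`, and (in `metadata()`) the analytic per-type expected
#' empirical means `expectedTypeMeans` (genes x types,
#' `p_gt * mean(library size in type)`), against which tests compare the
#' empirical means in closed form.
#'
#' @param config a [SynthConfig-class].
#' @return a list with elements `sce` (SingleCellExperiment) and `truth`
#'   (a [GroundTruth-class] with `cellLabels` and `markerCatalog` filled).
#' @examples
#' out <- generateCounts(synthConfig(seed = 7, nGenes = 300,
#'   cellTypeSizes = c(neuron = 40, astrocyte = 30), nMarkersPerType = 5))
#' dim(out$sce)
#' table(out$truth@cellLabels)
#' @export
generateCounts <- function(config) {
  validObject(config)
  .setSubstream(config, "counts")
  nG <- config@nGenes
  sizes <- config@cellTypeSizes
  types <- names(sizes)
  nCells <- sum(sizes)
  genes <- sprintf("G%05d", seq_len(nG))

  ## gene-level baseline means, log-normal
  base <- rlnorm(nG, meanlog = 0, sdlog = 1)

  ## disjoint marker sets
  markerIdx <- sample.int(nG, config@nMarkersPerType * length(types))
  catalog <- split(genes[markerIdx],
                   rep(types, each = config@nMarkersPerType))
  catalog <- catalog[types]
  markerBlocks <- split(markerIdx, rep(types, each = config@nMarkersPerType))

  ## per-type relative abundances
  probs <- vapply(types, function(t) {
    m <- base
    m[markerBlocks[[t]]] <- m[markerBlocks[[t]]] * 2^config@markerLog2Effect
    m / sum(m)
  }, numeric(nG))

  cellType <- rep(types, times = sizes)
  cellIds <- sprintf("C%05d", seq_len(nCells))
  libSize <- sample(seq(config@librarySizeRange[1], config@librarySizeRange[2]),
                    nCells, replace = TRUE)

  mu <- probs[, cellType, drop = FALSE] *
    matrix(libSize, nrow = nG, ncol = nCells, byrow = TRUE)
  counts <- matrix(rnbinom(nG * nCells, mu = mu,
                           size = 1 / config@baselineDispersion),
                   nrow = nG, dimnames = list(genes, cellIds))

  ## mitochondrial fraction correlated with library size
  zLib <- as.numeric(scale(log(libSize)))
  if (any(!is.finite(zLib))) zLib <- rep(0, nCells)
  percentMito <- pmin(pmax(5 + 2 * zLib + rnorm(nCells, sd = 1), 0.1), 40)

  expectedTypeMeans <- vapply(types, function(t) {
    probs[, t] * mean(libSize[cellType == t])
  }, numeric(nG))
  rownames(expectedTypeMeans) <- genes

  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(
      donor = sample(sprintf("donor%02d", 1:8), nCells, replace = TRUE),
      region = sample(c("ACC", "MTG", "VISp"), nCells, replace = TRUE),
      percent_mito = percentMito,
      row.names = cellIds))
  S4Vectors::metadata(sce)$expectedTypeMeans <- expectedTypeMeans
  S4Vectors::metadata(sce)$librarySize <- setNames(libSize, cellIds)

  truth <- new("GroundTruth",
               cellLabels = setNames(cellType, cellIds),
               markerCatalog = catalog)
  list(sce = sce, truth = truth)
}

#' Generate every synthetic input of the study at once
#'
#' Convenience driver that runs all generators in order, threading the
#' ground truth through them: counts -> variant table -> exon models ->
#' pLI -> spatiotemporal grid -> sorted-cell reference.
#'
#' @param config a [SynthConfig-class].
#' @return a list with `sce`, `variants`, `exons`, `pli`, `spatiotemporal`,
#'   `sorted` and the final `truth`.
#' @examples
#' syn <- generateAll(synthConfig(seed = 3, nGenes = 300,
#'   cellTypeSizes = c(neuron = 30, astrocyte = 30), nMarkersPerType = 5,
#'   variantCategoryCounts = c("de_novo:nonsense" = 50), nLofGenes = NA))
#' names(syn)
#' @export
generateAll <- function(config) {
  cnt <- generateCounts(config)
  vt <- generateVariantTable(config, cnt$truth)
  ex <- generateExonModels(config, vt$truth)
  pli <- generatePli(config, ex$truth)
  st <- generateSpatiotemporal(config, pli$truth)
  so <- generateSortedCellReference(config, st$truth)
  list(sce = cnt$sce, variants = vt$variants, exons = ex$exons,
       pli = pli$pli, spatiotemporal = st$spatiotemporal,
       sorted = so$sorted, truth = so$truth)
}
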