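#' Generate a gene x (region, period) developmental expression grid
#'
#' Emulates a BrainSpan-style RPKM grid: each gene gets a log-normal
#' baseline level shared across the grid, multiplied by per-cell
#' log-normal noise.  The prenatally biased genes (by default the unique
#' de novo LOF gene set recorded in the truth; a fresh random set of 100
#' genes if the truth has none) are boosted by `2^prenatalBiasLog2` in the
#' prenatal period of the designated regions (DFC and V1C analogues).
#'
#' @param config a [SynthConfig-class]; a `regions` vector not of length
#'   16 draws a warning but is used as given.
#' @param truth a [GroundTruth-class]; its `prenatalBiasedGenes` are
#'   boosted (and recorded if they had to be drawn here).
#' @param biasRegions regions whose prenatal column is boosted.
#' @return list with `spatiotemporal`
#'   (a [SummarizedExperiment::SummarizedExperiment], assay `rpkm`,
#'   genes x (regions x periods), `colData` columns `region`, `period`)
#'   and the updated `truth`.
#' @export
generateSpatiotemporal <- function(config, truth,
                                   biasRegions = c("DFC", "V1C")) {
  validObject(config)
  .setSubstream(config, "spatiotemporal")
  if (length(config@regions) != 16L)
    warning(sprintf("expected 16 regions, got %d; proceeding",
                    length(config@regions)))
  genes <- .geneIds(config)
  regions <- config@regions
  periods <- config@periods
  grid <- expand.grid(region = regions, period = periods,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  nCol <- nrow(grid)

  base <- rlnorm(config@nGenes, meanlog = 3, sdlog = 1)
  mat <- base * matrix(2^rnorm(config@nGenes * nCol, sd = 0.25),
                       nrow = config@nGenes)
  dimnames(mat) <- list(genes, paste(grid$region, grid$period, sep = "."))

  biased <- intersect(truth@prenatalBiasedGenes, genes)
  if (!length(biased)) {
    biased <- sample(genes, min(100L, config@nGenes))
    truth@prenatalBiasedGenes <- biased
  }
  boostCols <- which(grid$period == periods[1] & grid$region %in% biasRegions)
  if (length(boostCols) && config@prenatalBiasLog2 != 0)
    mat[biased, boostCols] <- mat[biased, boostCols] *
      2^config@prenatalBiasLog2

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(rpkm = mat),
    colData = S4Vectors::DataFrame(region = grid$region,
                                   period = grid$period,
                                   row.names = colnames(mat)))
  list(spatiotemporal = se, truth = truth)
}

#' Generate a sorted-cell-type mean-expression reference
#'
#' Emulates a marker-sorted single-cell validation dataset: mean
#' expression per gene for neurons, astrocytes, oligodendrocytes,
#' microglia and OPC (fixed column order, neurons first as the fold-change
#' reference).  The planted astrocyte-restricted genes (the
#' enriched-program genes that received LOF variants, or a fresh random
#' set of 50 genes if the truth has none) have their astrocyte column
#' multiplied by `sortedRestrictionRatio`.  A per-gene detection fraction
#' (share of cells with signal) is stored in `rowData`.
#'
#' @param config a [SynthConfig-class].
#' @param truth a [GroundTruth-class]; `enrichedVariantGenes` is filled if
#'   empty.
#' @return list with `sorted`
#'   (a [SummarizedExperiment::SummarizedExperiment], assay `meanexpr`,
#'   genes x 5 cell types, `rowData$detection`) and the updated `truth`.
#' @export
generateSortedCellReference <- function(config, truth) {
  validObject(config)
  .setSubstream(config, "sorted")
  genes <- .geneIds(config)
  types <- .sortedCellTypes
  base <- rlnorm(config@nGenes, meanlog = 2, sdlog = 1)
  mat <- base * matrix(2^rnorm(config@nGenes * length(types), sd = 0.3),
                       nrow = config@nGenes)
  dimnames(mat) <- list(genes, types)

  restricted <- intersect(truth@enrichedVariantGenes, genes)
  if (!length(restricted)) {
    restricted <- sample(genes, min(50L, config@nGenes))
    truth@enrichedVariantGenes <- restricted
  }
  mat[restricted, "astrocytes"] <- mat[restricted, "astrocytes"] *
    config@sortedRestrictionRatio

  detection <- runif(config@nGenes, 0.3, 1)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(meanexpr = mat),
    rowData = S4Vectors::DataFrame(detection = detection,
                                   row.names = genes))
  list(sorted = se, truth = truth)
}
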