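#' @import methods
#' @importFrom stats coef glm lm loess median pchisq phyper prcomp predict
#'   p.adjust prop.test quantile rbinom rlnorm rnbinom rnorm rpois runif sd
#'   t.test var wilcox.test qlnorm binomial setNames complete.cases
#' @importFrom utils head read.delim write.table combn
NULL

## ---------------------------------------------------------------------------
## SynthConfig
## ---------------------------------------------------------------------------

#' Configuration for the synthetic-data generators
#'
#' A `SynthConfig` holds every knob of the synthetic ASD single-cell /
#' variant / constraint study: the planted cell types and their marker
#' genes, the negative-binomial count model, the curated-variant category
#' counts, the constrained-exon and high-pLI fractions, and the
#' spatiotemporal grid (16 brain regions by 3 developmental periods).
#' Defaults reproduce the study conditions used throughout the test suite:
#' 500 nuclei over five brain cell types, 2,000 genes, and a variant
#' landscape with the published category totals (1,087 de novo LOF records
#' among 10,565 de novo exonic/splicing variants, 169,580 records overall).
#'
#' @slot seed integer; master seed. Each generator derives an independent
#'   substream (`seed + fixed offset`) so adding one component never
#'   perturbs another.
#' @slot nGenes integer; number of genes.
#' @slot cellTypeSizes named integer; cells per planted type.
#' @slot nMarkersPerType integer; planted markers per type (disjoint sets).
#' @slot markerLog2Effect numeric; log2 mean shift of a marker in its home
#'   type.
#' @slot baselineDispersion numeric; NB dispersion (size = 1/dispersion).
#' @slot librarySizeRange integer length-2; per-cell library sizes are
#'   drawn uniformly from this range.
#' @slot fracCriticalExons numeric in \[0,1\]; fraction of exons planted as
#'   critical (highly expressed, mutation-depleted).
#' @slot fracHighPli numeric in \[0,1\]; fraction of genes given pLI >= 0.9.
#' @slot variantCategoryCounts named integer; requested records per
#'   `"inheritance:effect"` category.
#' @slot nLofGenes integer; number of unique genes the de novo LOF records
#'   are spread over (surjective allocation), or `NA` for free weighted
#'   sampling.
#' @slot enrichedProgram character; cell type whose marker genes receive
#'   excess de novo LOF variants.
#' @slot enrichmentMultiplier numeric >= 1; sampling-weight multiplier on
#'   the enriched program's markers.
#' @slot regions character; region labels for the spatiotemporal grid
#'   (16 expected; a different length draws a warning).
#' @slot periods character length-3, ordered
#'   (prenatal, early_childhood, adult).
#' @slot prenatalBiasLog2 numeric; log2 boost of prenatal expression for
#'   the biased genes in the designated regions (DFC, V1C analogues).
#' @slot sortedRestrictionRatio numeric; astrocyte/neuron expression ratio
#'   for the planted astrocyte-restricted genes in the sorted-cell
#'   reference.
#'
#' @seealso [synthConfig()] for the user-facing constructor,
#'   [generateAll()] to materialise every input at once.
#' @exportClass SynthConfig
setClass("SynthConfig",
  representation(
    seed = "integer",
    nGenes = "integer",
    cellTypeSizes = "integer",
    nMarkersPerType = "integer",
    markerLog2Effect = "numeric",
    baselineDispersion = "numeric",
    librarySizeRange = "integer",
    fracCriticalExons = "numeric",
    fracHighPli = "numeric",
    variantCategoryCounts = "integer",
    nLofGenes = "integer",
    enrichedProgram = "character",
    enrichmentMultiplier = "numeric",
    regions = "character",
    periods = "character",
    prenatalBiasLog2 = "numeric",
    sortedRestrictionRatio = "numeric"
  )
)

setValidity("SynthConfig", function(object) {
  msg <- character()
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "'seed' must be a single integer")
  if (object@nGenes < 1L) msg <- c(msg, "'nGenes' must be positive")
  if (length(object@cellTypeSizes) &&
      (is.null(names(object@cellTypeSizes)) ||
       any(!nzchar(names(object@cellTypeSizes)))))
    msg <- c(msg, "'cellTypeSizes' must be named")
  bad <- names(object@cellTypeSizes)[object@cellTypeSizes < 1L]
  if (length(bad))
    msg <- c(msg, sprintf("cell type(s) with size 0: %s",
                          paste(bad, collapse = ", ")))
  if (object@nMarkersPerType < 1L)
    msg <- c(msg, "'nMarkersPerType' must be positive")
  if (object@nMarkersPerType * length(object@cellTypeSizes) > object@nGenes)
    msg <- c(msg, "marker sets exceed the gene universe (must be disjoint)")
  if (object@baselineDispersion <= 0)
    msg <- c(msg, "'baselineDispersion' must be positive")
  if (length(object@librarySizeRange) != 2L ||
      any(object@librarySizeRange < 1L) ||
      diff(object@librarySizeRange) < 0)
    msg <- c(msg, "'librarySizeRange' must be an increasing positive pair")
  for (p in c("fracCriticalExons", "fracHighPli")) {
    v <- slot(object, p)
    if (v < 0 || v > 1) msg <- c(msg, sprintf("'%s' must lie in [0,1]", p))
  }
  if (any(object@variantCategoryCounts < 0L))
    msg <- c(msg, "'variantCategoryCounts' must be non-negative")
  if (length(object@variantCategoryCounts)) {
    parsed <- strsplit(names(object@variantCategoryCounts), ":", fixed = TRUE)
    ok <- vapply(parsed, function(x) {
      length(x) == 2L && x[1] %in% .inheritanceVocab && x[2] %in% .effectVocab
    }, logical(1))
    if (!all(ok))
      msg <- c(msg, sprintf(
        "variant category label(s) outside the controlled vocabulary: %s",
        paste(names(object@variantCategoryCounts)[!ok], collapse = ", ")))
  }
  if (object@enrichmentMultiplier < 1)
    msg <- c(msg, "'enrichmentMultiplier' must be >= 1")
  if (length(object@periods) != 3L)
    msg <- c(msg, "'periods' must have length 3")
  if (length(msg)) msg else TRUE
})

.effectVocab <- c("nonsense", "frameshift", "splicing", "missense",
                  "synonymous", "noncoding", "other")
.inheritanceVocab <- c("de_novo", "inherited", "unknown")
.lofEffects <- c("nonsense", "frameshift", "splicing")
.sortedCellTypes <- c("neurons", "astrocytes", "oligodendrocytes",
                      "microglia", "OPC")

## The 16 BrainSpan-style region labels (AMY..HIP) and the three
## developmental periods used throughout.
.defaultRegions <- c("AMY", "CBC", "V1C", "STC", "IPC", "A1C", "S1C", "M1C",
                     "STR", "DFC", "MFC", "VFC", "OFC", "MD", "ITC", "HIP")
.defaultPeriods <- c("prenatal", "early_childhood", "adult")

## ---------------------------------------------------------------------------
## GroundTruth
## ---------------------------------------------------------------------------

#' Planted ground truth of a synthetic study
#'
#' Records everything the generators planted, so downstream recovery can be
#' scored: cell labels, marker catalogue, per-stage critical-exon flags,
#' high-pLI genes, the genes of the LOF-enriched cell-type program that
#' actually received variants, and the prenatally biased genes.
#'
#' @slot cellLabels named character; cell id -> planted cell type.
#' @slot markerCatalog named list of character; cell type -> marker genes
#'   (disjoint across types).
#' @slot criticalExonFlags data.frame with columns `gene`, `exon_index`,
#'   `stage` listing the planted critical (gene, exon, stage) triples.
#' @slot highPliGenes character; genes planted with pLI >= 0.9.
#' @slot enrichedVariantGenes character; enriched-program marker genes that
#'   received at least one de novo LOF record.
#' @slot prenatalBiasedGenes character; genes given the prenatal expression
#'   boost (the unique de novo LOF gene set once a variant table exists).
#'
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(
    cellLabels = "character",
    markerCatalog = "list",
    criticalExonFlags = "data.frame",
    highPliGenes = "character",
    enrichedVariantGenes = "character",
    prenatalBiasedGenes = "character"
  ),
  prototype(
    cellLabels = character(),
    markerCatalog = list(),
    criticalExonFlags = data.frame(gene = character(),
                                   exon_index = integer(),
                                   stage = character()),
    highPliGenes = character(),
    enrichedVariantGenes = character(),
    prenatalBiasedGenes = character()
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  mk <- unlist(object@markerCatalog, use.names = FALSE)
  if (anyDuplicated(mk))
    msg <- c(msg, "marker sets of distinct cell types must be disjoint")
  need <- c("gene", "exon_index", "stage")
  if (!all(need %in% names(object@criticalExonFlags)))
    msg <- c(msg, "'criticalExonFlags' needs columns gene/exon_index/stage")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## GeneSet
## ---------------------------------------------------------------------------

#' A named set of gene symbols
#'
#' The light-weight currency of every enrichment analysis in the package:
#' a unique set of gene symbols, a name, and free-text provenance.
#'
#' @slot name character; set name (GMT first column).
#' @slot genes character; unique, non-empty gene symbols.
#' @slot provenance character; free-text origin (GMT second column).
#'
#' @seealso [geneSet()], [readGmt()], [writeGmt()]
#' @exportClass GeneSet
setClass("GeneSet",
  representation(name = "character", genes = "character",
                 provenance = "character"),
  prototype(provenance = "")
)

setValidity("GeneSet", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a non-empty string")
  if (anyDuplicated(object@genes))
    msg <- c(msg, "'genes' must be unique")
  if (length(object@genes) && any(!nzchar(object@genes)))
    msg <- c(msg, "'genes' must be non-empty symbols")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## ClusterLabeling
## ---------------------------------------------------------------------------

#' Cluster assignment of cells
#'
#' Labels are 0-based integers ordered by decreasing cluster size (cluster
#' 0 is the largest), together with the parameters that produced them.
#'
#' @slot labels named integer; cell id -> cluster id (0-based).
#' @slot params list; at least `resolution`, `n_pcs`, `knn_k`, `seed`.
#' @slot sizes named integer; cluster id -> cell count.
#'
#' @exportClass ClusterLabeling
setClass("ClusterLabeling",
  representation(labels = "integer", params = "list", sizes = "integer")
)

setValidity("ClusterLabeling", function(object) {
  msg <- character()
  if (is.null(names(object@labels)))
    msg <- c(msg, "'labels' must be named by cell id")
  if (sum(object@sizes) != length(object@labels))
    msg <- c(msg, "'sizes' must sum to the number of labelled cells")
  if (length(object@sizes) && any(object@sizes < 1L))
    msg <- c(msg, "every cluster must contain at least one cell")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## CriticalExonMatrix
## ---------------------------------------------------------------------------

#' Per-stage critical-exon calls
#'
#' Boolean flags for every (gene, exon, stage) in the input exon models,
#' plus the quantile parameters used.  An exon is critical at a stage when
#' its expression at that stage is at or above the `q_e` expression
#' quantile while its non-synonymous mutation burden (mutations per bp) is
#' at or below the `q_b` burden quantile.
#'
#' @slot flags data.frame with columns `gene`, `exon_index`, `stage`,
#'   `flag` covering every input exon at every requested stage.
#' @slot params list with `q_e` and `q_b`.
#'
#' @seealso [criticalExons()], [ceGeneSet()]
#' @exportClass CriticalExonMatrix
setClass("CriticalExonMatrix",
  representation(flags = "data.frame", params = "list")
)

setValidity("CriticalExonMatrix", function(object) {
  need <- c("gene", "exon_index", "stage", "flag")
  if (!all(need %in% names(object@flags)))
    return("'flags' needs columns gene/exon_index/stage/flag")
  TRUE
})
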