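#' Accessors
#'
#' Small accessor generics for the package's S4 classes; slots are never
#' reached into directly by user code.
#'
#' @param x an object.
#' @param ... further arguments (unused).
#' @return `geneIds()` a character vector; `setName()` a string;
#'   `clusterLabels()` a named integer vector; `clusterSizes()` a named
#'   integer vector; `clusterParams()` a list; `ceFlags()` a data.frame.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x, ...) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("setName", function(x, ...) standardGeneric("setName"))

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x, ...) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setGeneric("clusterSizes", function(x, ...) standardGeneric("clusterSizes"))

#' @rdname accessors
#' @export
setGeneric("clusterParams", function(x, ...) standardGeneric("clusterParams"))

#' @rdname accessors
#' @export
setGeneric("ceFlags", function(x, ...) standardGeneric("ceFlags"))

#' @rdname accessors
#' @export
setMethod("geneIds", "GeneSet", function(x, ...) x@genes)

#' @rdname accessors
#' @export
setMethod("setName", "GeneSet", function(x, ...) x@name)

#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusterLabeling", function(x, ...) x@labels)

#' @rdname accessors
#' @export
setMethod("clusterSizes", "ClusterLabeling", function(x, ...) x@sizes)

#' @rdname accessors
#' @export
setMethod("clusterParams", "ClusterLabeling", function(x, ...) x@params)

#' @rdname accessors
#' @export
setMethod("ceFlags", "CriticalExonMatrix", function(x, ...) x@flags)

#' Construct a GeneSet
#'
#' @param name set name.
#' @param genes character vector of gene symbols; duplicates are removed.
#' @param provenance free-text origin of the set.
#' @return a [GeneSet-class] object.
#' @examples
#' gs <- geneSet("astro_markers", c("GFAP", "AQP4", "GFAP"))
#' geneIds(gs)
#' @export
geneSet <- function(name, genes, provenance = "") {
  new("GeneSet", name = name, genes = unique(as.character(genes)),
      provenance = provenance)
}

setMethod("show", "GeneSet", function(object) {
  cat(sprintf("GeneSet '%s': %d genes", object@name, length(object@genes)))
  if (nzchar(object@provenance))
    cat(sprintf(" (%s)", object@provenance))
  cat("\n")
})

setMethod("show", "ClusterLabeling", function(object) {
  cat(sprintf("ClusterLabeling: %d cells in %d clusters\n",
              length(object@labels), length(object@sizes)))
  cat("sizes:", paste(sprintf("%s=%d", names(object@sizes), object@sizes),
                      collapse = ", "), "\n")
  p <- object@params
  if (length(p))
    cat("params:", paste(sprintf("%s=%s", names(p),
                                 vapply(p, format, character(1))),
                         collapse = ", "), "\n")
})

setMethod("show", "SynthConfig", function(object) {
  cat("SynthConfig\n")
  cat(sprintf("  seed %d | %d genes | %d cells in %d types\n",
              object@seed, object@nGenes, sum(object@cellTypeSizes),
              length(object@cellTypeSizes)))
  cat(sprintf("  markers/type %d at log2 effect %.2f | NB dispersion %.2f\n",
              object@nMarkersPerType, object@markerLog2Effect,
              object@baselineDispersion))
  cat(sprintf("  %d variant records in %d categories | enriched program '%s' (x%.1f)\n",
              sum(object@variantCategoryCounts),
              length(object@variantCategoryCounts),
              object@enrichedProgram, object@enrichmentMultiplier))
  cat(sprintf("  grid %d regions x %d periods | prenatal bias %.1f log2\n",
              length(object@regions), length(object@periods),
              object@prenatalBiasLog2))
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth\n")
  cat(sprintf("  %d labelled cells | %d marker sets | %d critical exon flags\n",
              length(object@cellLabels), length(object@markerCatalog),
              nrow(object@criticalExonFlags)))
  cat(sprintf("  %d high-pLI genes | %d enriched variant genes | %d prenatal-biased genes\n",
              length(object@highPliGenes), length(object@enrichedVariantGenes),
              length(object@prenatalBiasedGenes)))
})

setMethod("show", "CriticalExonMatrix", function(object) {
  f <- object@flags
  cat(sprintf("CriticalExonMatrix: %d exon-stage entries, %d flagged (q_e=%.2f, q_b=%.2f)\n",
              nrow(f), sum(f$flag), object@params$q_e, object@params$q_b))
})
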