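#' Create a synthetic-study configuration
#'
#' Builds a validated [SynthConfig-class]. The defaults are the study
#' conditions used by the test suite and the acceptance analysis: 500
#' nuclei over the five primary brain cell types (neuron-dominated, as in
#' adult cortical atlases), 2,000 genes, 20 disjoint markers per type with
#' a 2 log2 home-type shift, an overdispersed negative-binomial count
#' model, and a curated-variant landscape whose category totals equal the
#' published compilation (169,580 records: 156,688 de novo of which 10,565
#' are exonic/splicing, split into 6,651 missense, 1,087 LOF -- nonsense
#' 470, frameshift 414, splicing 203 -- and 2,827 synonymous/other; 1,463
#' rare inherited; the remainder of unknown inheritance), with the 1,087
#' de novo LOF records spread over 852 unique genes.
#'
#' @param seed integer master seed.
#' @param nGenes number of genes.
#' @param cellTypeSizes named integer vector of cells per planted type.
#' @param nMarkersPerType planted marker genes per type.
#' @param markerLog2Effect log2 mean shift of a marker in its home type.
#' @param baselineDispersion negative-binomial dispersion (size = 1/disp).
#' @param librarySizeRange integer pair; uniform per-cell library sizes.
#' @param fracCriticalExons fraction of exons planted critical.
#' @param fracHighPli fraction of genes with planted pLI >= 0.9.
#' @param variantCategoryCounts named integer vector,
#'   names `"inheritance:effect"` over the controlled vocabularies
#'   (inheritance: de_novo/inherited/unknown; effect: nonsense/frameshift/
#'   splicing/missense/synonymous/noncoding/other).
#' @param nLofGenes unique genes the de novo LOF records must cover
#'   (surjective allocation), or `NA` for free weighted sampling.
#' @param enrichedProgram cell type whose markers receive excess LOF
#'   variants.
#' @param enrichmentMultiplier sampling-weight multiplier (>= 1) on the
#'   enriched program's markers.
#' @param regions spatiotemporal region labels (16 expected).
#' @param periods ordered developmental periods (length 3).
#' @param prenatalBiasLog2 log2 prenatal boost for biased genes in the
#'   DFC/V1C analogue regions.
#' @param sortedRestrictionRatio astrocyte/neuron ratio for planted
#'   astrocyte-restricted genes in the sorted-cell reference.
#' @return a [SynthConfig-class] object.
#' @examples
#' cfg <- synthConfig(seed = 7, nGenes = 400,
#'                    cellTypeSizes = c(neuron = 60, astrocyte = 40),
#'                    nMarkersPerType = 10)
#' cfg
#' @export
synthConfig <- function(seed = 1L,
                        nGenes = 2000L,
                        cellTypeSizes = c(neuron = 200L, astrocyte = 100L,
                                          oligodendrocyte = 100L,
                                          microglia = 50L, OPC = 50L),
                        nMarkersPerType = 20L,
                        markerLog2Effect = 2,
                        baselineDispersion = 0.3,
                        librarySizeRange = c(10000L, 30000L),
                        fracCriticalExons = 0.1,
                        fracHighPli = 0.1,
                        variantCategoryCounts = c(
                          "de_novo:nonsense"   = 470L,
                          "de_novo:frameshift" = 414L,
                          "de_novo:splicing"   = 203L,
                          "de_novo:missense"   = 6651L,
                          "de_novo:synonymous" = 2827L,
                          "de_novo:noncoding"  = 146123L,
                          "inherited:noncoding" = 1463L,
                          "unknown:noncoding"  = 11429L),
                        nLofGenes = 852L,
                        enrichedProgram = "astrocyte",
                        enrichmentMultiplier = 10,
                        regions = .defaultRegions,
                        periods = .defaultPeriods,
                        prenatalBiasLog2 = 2,
                        sortedRestrictionRatio = 8) {
  sizes <- as.integer(cellTypeSizes)
  names(sizes) <- names(cellTypeSizes)
  counts <- as.integer(variantCategoryCounts)
  names(counts) <- names(variantCategoryCounts)
  new("SynthConfig",
      seed = as.integer(seed),
      nGenes = as.integer(nGenes),
      cellTypeSizes = sizes,
      nMarkersPerType = as.integer(nMarkersPerType),
      markerLog2Effect = as.numeric(markerLog2Effect),
      baselineDispersion = as.numeric(baselineDispersion),
      librarySizeRange = as.integer(librarySizeRange),
      fracCriticalExons = as.numeric(fracCriticalExons),
      fracHighPli = as.numeric(fracHighPli),
      variantCategoryCounts = counts,
      nLofGenes = as.integer(nLofGenes),
      enrichedProgram = as.character(enrichedProgram),
      enrichmentMultiplier = as.numeric(enrichmentMultiplier),
      regions = as.character(regions),
      periods = as.character(periods),
      prenatalBiasLog2 = as.numeric(prenatalBiasLog2),
      sortedRestrictionRatio = as.numeric(sortedRestrictionRatio))
}

## Fixed substream offsets: one global seed drives independent per-component
## substreams, so adding a component never perturbs the others.
.substream <- c(counts = 0L, variants = 101L, exons = 202L, pli = 303L,
                spatiotemporal = 404L, sorted = 505L)

.setSubstream <- function(config, component) {
  set.seed(config@seed + .substream[[component]])
}
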