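# small study configurations reused across tests

smallConfig <- function(seed = 1L, ...) {
  args <- list(
    seed = seed, nGenes = 600L,
    cellTypeSizes = c(neuron = 120L, astrocyte = 60L, oligodendrocyte = 60L),
    nMarkersPerType = 15L,
    variantCategoryCounts = c("de_novo:nonsense" = 120L,
                              "de_novo:frameshift" = 100L,
                              "de_novo:splicing" = 40L,
                              "de_novo:missense" = 300L,
                              "inherited:noncoding" = 50L),
    nLofGenes = NA_integer_)
  utils::modifyList(args, list(...))
}

smallStudy <- function(seed = 1L, ...) {
  generateAll(do.call(synthConfig, smallConfig(seed, ...)))
}
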