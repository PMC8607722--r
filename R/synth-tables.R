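.geneIds <- function(config) sprintf("G%05d", seq_len(config@nGenes))

#' Generate a curated-variant table with a planted enriched program
#'
#' Emulates a multi-study compilation of ASD variants: exactly the
#' requested number of records per `"inheritance:effect"` category.  Genes
#' for coding/splicing records are sampled from the gene universe; for the
#' de novo LOF categories (nonsense, frameshift, splicing) the sampling
#' weight of the enriched program's marker genes is multiplied by
#' `enrichmentMultiplier`.  When `nLofGenes` is set, the de novo LOF
#' records are allocated surjectively over a weighted sample of exactly
#' that many genes, so the unique de novo LOF gene count of the table is
#' `nLofGenes` by construction (emulating a curation with a known number
#' of impacted genes).  Noncoding records carry an empty gene symbol.
#'
#' @param config a [SynthConfig-class].
#' @param truth the [GroundTruth-class] from [generateCounts()] (its
#'   marker catalogue defines the enriched program); may be an empty
#'   `GroundTruth` if no counts were generated.
#' @return list with `variants` (data.frame: `variant_id`, `gene`,
#'   `effect`, `inheritance`, `case_id`) and the updated `truth`
#'   (`enrichedVariantGenes`, `prenatalBiasedGenes` filled).
#' @examples
#' cfg <- synthConfig(seed = 2, nGenes = 500, variantCategoryCounts =
#'   c("de_novo:nonsense" = 30, "de_novo:missense" = 50), nLofGenes = NA)
#' vt <- generateVariantTable(cfg, new("GroundTruth"))
#' table(vt$variants$effect)
#' @export
generateVariantTable <- function(config, truth) {
  validObject(config)
  .setSubstream(config, "variants")
  counts <- config@variantCategoryCounts
  cols <- c("variant_id", "gene", "effect", "inheritance", "case_id")
  if (!length(counts) || sum(counts) == 0L) {
    empty <- data.frame(variant_id = character(), gene = character(),
                        effect = character(), inheritance = character(),
                        case_id = character(), stringsAsFactors = FALSE)
    truth@prenatalBiasedGenes <- character()
    return(list(variants = empty, truth = truth))
  }
  parsed <- strsplit(names(counts), ":", fixed = TRUE)
  inh <- vapply(parsed, `[`, character(1), 1L)
  eff <- vapply(parsed, `[`, character(1), 2L)
  bad <- !(inh %in% .inheritanceVocab & eff %in% .effectVocab)
  if (any(bad))
    stop("variant category label(s) outside the controlled vocabulary: ",
         paste(names(counts)[bad], collapse = ", "))

  genes <- .geneIds(config)
  program <- truth@markerCatalog[[config@enrichedProgram]]
  if (is.null(program)) program <- character()
  w <- rep(1, config@nGenes)
  w[genes %in% program] <- config@enrichmentMultiplier

  inheritance <- rep(inh, times = counts)
  effect <- rep(eff, times = counts)
  n <- length(effect)
  gene <- character(n)

  isLof <- effect %in% .lofEffects & inheritance == "de_novo"
  isCoding <- effect %in% c("nonsense", "frameshift", "splicing", "missense",
                            "synonymous", "other")

  nLof <- sum(isLof)
  if (nLof > 0L) {
    if (!is.na(config@nLofGenes)) {
      k <- config@nLofGenes
      if (k > config@nGenes)
        stop("'nLofGenes' exceeds the gene universe")
      if (k > nLof)
        stop(sprintf(
          "'nLofGenes' (%d) exceeds the number of de novo LOF records (%d)",
          k, nLof))
      pool <- sample(genes, k, prob = w)
      extra <- if (nLof > k)
        sample(pool, nLof - k, replace = TRUE, prob = w[match(pool, genes)])
      else character()
      gene[isLof] <- sample(c(pool, extra))
    } else {
      gene[isLof] <- sample(genes, nLof, replace = TRUE, prob = w)
    }
  }
  nOther <- sum(isCoding & !isLof)
  if (nOther > 0L)
    gene[isCoding & !isLof] <- sample(genes, nOther, replace = TRUE)

  variants <- data.frame(
    variant_id = sprintf("V%06d", seq_len(n)),
    gene = gene,
    effect = effect,
    inheritance = inheritance,
    case_id = sprintf("case%05d", sample.int(40122L, n, replace = TRUE)),
    stringsAsFactors = FALSE)

  lofGenes <- unique(gene[isLof])
  truth@enrichedVariantGenes <- intersect(program, lofGenes)
  truth@prenatalBiasedGenes <- lofGenes
  list(variants = variants[, cols], truth = truth)
}

#' Generate exon models with planted critical exons
#'
#' Each gene receives 1-20 exons with length >= 30 bp, per-stage (PN, EC,
#' AD) log-normal expression, and a Poisson non-synonymous mutation count
#' proportional to length (baseline rate 0.5 per bp, a gnomAD-scale
#' density).  A fraction `fracCriticalExons` of exons is planted critical:
#' their expression at all three stages is drawn from the upper quartile
#' of the baseline log-normal and shifted one further doubling (keeping
#' the high-expression stratum identifiable after mixing), and their
#' mutation count uses a quarter of the baseline rate.  Planted flags are
#' recorded in the truth per stage.
#'
#' @param config a [SynthConfig-class].
#' @param truth a [GroundTruth-class] to update.
#' @return list with `exons` (data.frame: `gene`, `exon_index`,
#'   `length_bp`, `nonsyn_count`, `expr_PN`, `expr_EC`, `expr_AD`) and the
#'   updated `truth` (`criticalExonFlags` filled).
#' @export
generateExonModels <- function(config, truth) {
  validObject(config)
  .setSubstream(config, "exons")
  genes <- .geneIds(config)
  nExons <- sample(1:20, config@nGenes, replace = TRUE)
  gene <- rep(genes, times = nExons)
  exonIndex <- unlist(lapply(nExons, seq_len), use.names = FALSE)
  n <- length(gene)
  lengthBp <- pmax(30L, as.integer(round(rlnorm(n, log(150), 0.7))))

  expr <- vapply(c("PN", "EC", "AD"),
                 function(s) rlnorm(n, meanlog = 2, sdlog = 1),
                 numeric(n))
  nonsyn <- rpois(n, 0.5 * lengthBp)

  nPlant <- round(config@fracCriticalExons * n)
  if (nPlant > 0L) {
    planted <- sample.int(n, nPlant)
    for (j in 1:3)
      expr[planted, j] <- qlnorm(0.75 + 0.25 * runif(nPlant),
                                 meanlog = 2, sdlog = 1) * 2
    nonsyn[planted] <- rpois(nPlant, 0.125 * lengthBp[planted])
    truth@criticalExonFlags <- data.frame(
      gene = rep(gene[planted], each = 3L),
      exon_index = rep(exonIndex[planted], each = 3L),
      stage = rep(c("PN", "EC", "AD"), times = nPlant),
      stringsAsFactors = FALSE)
  } else {
    truth@criticalExonFlags <- data.frame(gene = character(),
                                          exon_index = integer(),
                                          stage = character())
  }

  exons <- data.frame(gene = gene, exon_index = exonIndex,
                      length_bp = lengthBp, nonsyn_count = nonsyn,
                      expr_PN = expr[, 1], expr_EC = expr[, 2],
                      expr_AD = expr[, 3], stringsAsFactors = FALSE)
  list(exons = exons, truth = truth)
}

#' Generate gene-level pLI scores with a planted high-pLI stratum
#'
#' A fraction `fracHighPli` of genes receives pLI drawn uniformly from
#' \[0.9, 1\] (sampled preferentially, by `enrichmentMultiplier` weight, on
#' the enriched program's marker genes); every other gene receives pLI
#' uniform on \[0, 0.89\].  The two strata are disjoint around the 0.9
#' cutoff, so thresholding at 0.9 recovers the planted set exactly.
#'
#' @param config a [SynthConfig-class].
#' @param truth a [GroundTruth-class] to update.
#' @return list with `pli` (data.frame: `gene`, `pli`) and the updated
#'   `truth` (`highPliGenes` filled).
#' @export
generatePli <- function(config, truth) {
  validObject(config)
  .setSubstream(config, "pli")
  genes <- .geneIds(config)
  program <- truth@markerCatalog[[config@enrichedProgram]]
  w <- rep(1, config@nGenes)
  w[genes %in% program] <- config@enrichmentMultiplier
  nHigh <- round(config@fracHighPli * config@nGenes)
  pli <- runif(config@nGenes, 0, 0.89)
  high <- character()
  if (nHigh > 0L) {
    high <- sample(genes, nHigh, prob = w)
    pli[match(high, genes)] <- runif(nHigh, 0.9, 1)
  }
  truth@highPliGenes <- sort(high)
  list(pli = data.frame(gene = genes, pli = pli, stringsAsFactors = FALSE),
       truth = truth)
}
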