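#' Non-synonymous mutation burden of an exon
#'
#' Mutations per base pair: `nonsyn_count / length_bp`.
#'
#' @param nonsynCount non-negative mutation counts.
#' @param lengthBp positive exon lengths (bp).
#' @return numeric burden vector.
#' @examples
#' exonBurden(5, 100)
#' @export
exonBurden <- function(nonsynCount, lengthBp) {
  if (any(lengthBp <= 0)) stop("exon length must be positive")
  nonsynCount / lengthBp
}

#' Call critical exons by the expression/burden quadrant rule
#'
#' An exon is critical at a developmental stage when its expression at
#' that stage is at or above the `q_e` quantile of all exon expressions
#' at that stage (default: upper quartile) while its mutation burden
#' (mutations per bp) is at or below the `q_b` quantile of all burdens
#' (default: lower quartile).  Quantile thresholds are computed per
#' stage; flags for one stage are unaffected by the other stages'
#' expression values.
#'
#' @param exons data.frame with columns `gene`, `exon_index`,
#'   `length_bp`, `nonsyn_count` and `expr_<stage>` for each stage (see
#'   [generateExonModels()] / [readExonTsv()]); at least 20 exons.
#' @param stages stages to call (default PN, EC, AD).
#' @param q_e expression quantile (default 0.75).
#' @param q_b burden quantile (default 0.25).
#' @return a [CriticalExonMatrix-class] with flags for every
#'   (exon, stage).
#' @export
criticalExons <- function(exons, stages = c("PN", "EC", "AD"),
                          q_e = 0.75, q_b = 0.25) {
  if (nrow(exons) < 20L)
    stop("need at least 20 exons for meaningful quantiles")
  burden <- exonBurden(exons$nonsyn_count, exons$length_bp)
  bCut <- quantile(burden, q_b)
  flags <- lapply(stages, function(s) {
    col <- paste0("expr_", s)
    if (!col %in% names(exons))
      stop(sprintf("missing expression column '%s'", col))
    e <- exons[[col]]
    if (length(unique(e)) == 1L)
      stop(sprintf("all expressions equal at stage %s: degenerate quantiles",
                   s))
    eCut <- quantile(e, q_e)
    data.frame(gene = exons$gene, exon_index = exons$exon_index,
               stage = s, flag = e >= eCut & burden <= bCut,
               stringsAsFactors = FALSE)
  })
  new("CriticalExonMatrix", flags = do.call(rbind, flags),
      params = list(q_e = q_e, q_b = q_b))
}

#' Genes with at least one critical exon at a stage
#'
#' @param ceMatrix a [CriticalExonMatrix-class].
#' @param stage the stage to extract (e.g. `"PN"`).
#' @return a [GeneSet-class].
#' @export
ceGeneSet <- function(ceMatrix, stage) {
  f <- ceFlags(ceMatrix)
  f <- f[f$stage == stage & f$flag, , drop = FALSE]
  geneSet(paste0("ce_", stage), unique(f$gene),
          sprintf("genes with >= 1 critical exon at stage %s", stage))
}

#' Critical-exon enrichment of a cluster gene list (proportion test)
#'
#' Compares the critical-exon gene fraction among the cluster's genes
#' with the fraction among the rest of the universe, using the two-sample
#' proportion test (two-sided Pearson chi-square without continuity
#' correction, so that z^2 equals the 2x2 chi-square identically).  The
#' odds ratio is the sample OR of the induced 2x2 table.
#'
#' @param clusterGenes character vector of cluster genes (subset of
#'   `universe`, non-empty).
#' @param ceGenes critical-exon gene set (character or
#'   [GeneSet-class]).
#' @param universe background genes.
#' @param nameA,nameB labels recorded in the result.
#' @return one-row data.frame in the [fisherOverlap()] layout with
#'   `method = "proportion"`.
#' @export
ceEnrichment <- function(clusterGenes, ceGenes, universe,
                         nameA = "cluster", nameB = "ce") {
  if (is(ceGenes, "GeneSet")) {
    nameB <- setName(ceGenes)
    ceGenes <- geneIds(ceGenes)
  }
  universe <- unique(universe)
  clusterGenes <- unique(clusterGenes)
  if (!length(clusterGenes)) stop("empty cluster gene set")
  if (length(setdiff(clusterGenes, universe)))
    stop("cluster genes must be subsets of the universe")
  ceGenes <- intersect(unique(ceGenes), universe)
  rest <- setdiff(universe, clusterGenes)
  x1 <- length(intersect(clusterGenes, ceGenes))
  x2 <- length(intersect(rest, ceGenes))
  n1 <- length(clusterGenes); n2 <- length(rest)
  p <- if (x1 + x2 == 0 || x1 + x2 == n1 + n2) 1
       else suppressWarnings(
         prop.test(c(x1, x2), c(n1, n2), correct = FALSE)$p.value)
  data.frame(set_a = nameA, set_b = nameB,
             universe_size = length(universe),
             a_size = n1, b_size = length(ceGenes), overlap = x1,
             odds_ratio = .sampleOR(x1, n1 - x1, x2, n2 - x2),
             p = p, p_adj = NA_real_, method = "proportion",
             stringsAsFactors = FALSE)
}

#' pLI enrichment of a cluster gene list (Fisher)
#'
#' Hypergeometric enrichment of the high-pLI gene set (pLI >= `cutoff`,
#' default 0.9) within the cluster's genes.  Genes absent from the pLI
#' table are excluded from the universe (a message reports how many).
#'
#' @param clusterGenes character vector of cluster genes.
#' @param pliTable data.frame with columns `gene` and `pli`.
#' @param universe background genes.
#' @param cutoff high-pLI threshold (default 0.9).
#' @param nameA label for the cluster side of the result.
#' @return one-row data.frame in the [fisherOverlap()] layout.
#' @export
pliEnrichment <- function(clusterGenes, pliTable, universe, cutoff = 0.9,
                          nameA = "cluster") {
  universe <- unique(universe)
  scored <- intersect(universe, pliTable$gene)
  dropped <- length(universe) - length(scored)
  if (dropped > 0)
    message(sprintf("%d universe gene(s) missing from the pLI table; excluded",
                    dropped))
  high <- pliTable$gene[pliTable$pli >= cutoff]
  fisherOverlap(intersect(clusterGenes, scored),
                intersect(high, scored), scored,
                nameA = nameA, nameB = sprintf("pLI>=%.2g", cutoff))
}
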