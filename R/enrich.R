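.sampleOR <- function(n11, n10, n01, n00) {
  ## sample (cross-product) odds ratio; Haldane-Anscombe 0.5 only when a
  ## margin cell is zero, and only for the OR, never for the p-value
  if (any(c(n11, n10, n01, n00) == 0)) {
    if (n11 == 0) return(0)
    if (n10 == 0 || n01 == 0) return(Inf)
    n11 <- n11 + 0.5; n10 <- n10 + 0.5; n01 <- n01 + 0.5; n00 <- n00 + 0.5
  }
  (n11 * n00) / (n10 * n01)
}

#' Gene-set overlap test (hypergeometric)
#'
#' The generic overlap engine used by every enrichment analysis: given
#' two gene sets within a universe, computes the overlap, the sample odds
#' ratio of the induced 2x2 table, and the hypergeometric enrichment
#' p-value (upper tail, i.e. one-sided towards over-representation;
#' `alternative = "two.sided"` doubles the smaller tail).
#'
#' @param setA,setB character vectors of genes (or [GeneSet-class]
#'   objects); both must be subsets of `universe`.
#' @param universe character vector of background genes (>= 2).
#' @param alternative `"greater"` (enrichment, default) or
#'   `"two.sided"`.
#' @param nameA,nameB labels recorded in the result (default: the
#'   GeneSet names or deparsed arguments).
#' @return one-row data.frame: `set_a`, `set_b`, `universe_size`,
#'   `a_size`, `b_size`, `overlap`, `odds_ratio`, `p`, `p_adj` (NA until
#'   a batch correction), `method` ("fisher").
#' @examples
#' u <- sprintf("g%02d", 1:20)
#' fisherOverlap(u[1:5], u[3:7], u)
#' @export
fisherOverlap <- function(setA, setB, universe,
                          alternative = c("greater", "two.sided"),
                          nameA = NULL, nameB = NULL) {
  alternative <- match.arg(alternative)
  if (is(setA, "GeneSet")) { if (is.null(nameA)) nameA <- setName(setA)
                             setA <- geneIds(setA) }
  if (is(setB, "GeneSet")) { if (is.null(nameB)) nameB <- setName(setB)
                             setB <- geneIds(setB) }
  if (is.null(nameA)) nameA <- "set_a"
  if (is.null(nameB)) nameB <- "set_b"
  universe <- unique(universe)
  if (length(universe) < 2L) stop("universe must contain at least 2 genes")
  setA <- unique(setA); setB <- unique(setB)
  if (!length(setA) || !length(setB)) stop("empty gene set")
  if (length(setdiff(setA, universe)) || length(setdiff(setB, universe)))
    stop("gene sets must be subsets of the universe")
  N <- length(universe)
  a <- length(setA); b <- length(setB)
  k <- length(intersect(setA, setB))
  n11 <- k; n10 <- a - k; n01 <- b - k; n00 <- N - a - b + k
  pUpper <- phyper(k - 1, b, N - b, a, lower.tail = FALSE)
  p <- if (alternative == "greater") pUpper else {
    pLower <- phyper(k, b, N - b, a)
    min(1, 2 * min(pUpper, pLower))
  }
  data.frame(set_a = nameA, set_b = nameB, universe_size = N,
             a_size = a, b_size = b, overlap = k,
             odds_ratio = .sampleOR(n11, n10, n01, n00),
             p = p, p_adj = NA_real_, method = "fisher",
             stringsAsFactors = FALSE)
}

#' Batch enrichment of cluster DEG lists against gene sets
#'
#' Runs [fisherOverlap()] for every (cluster, gene set) pair and applies
#' the multiple-testing correction jointly over all tests in the batch.
#'
#' @param clusterGenes named list: cluster -> character vector of genes
#'   (e.g. consensus DEG lists).
#' @param geneSets named list of [GeneSet-class] objects or character
#'   vectors; duplicate names are an error.
#' @param universe background gene vector.
#' @param correction `"bonferroni"` (default) or `"BH"`.
#' @return data.frame with one row per test (columns of
#'   [fisherOverlap()], `p_adj` filled).
#' @export
batchEnrich <- function(clusterGenes, geneSets, universe,
                        correction = c("bonferroni", "BH")) {
  correction <- match.arg(correction)
  if (anyDuplicated(names(geneSets)))
    stop("duplicate gene set names: ",
         paste(unique(names(geneSets)[duplicated(names(geneSets))]),
               collapse = ", "))
  rows <- list()
  for (cl in names(clusterGenes)) {
    for (gs in names(geneSets)) {
      s <- geneSets[[gs]]
      genes <- if (is(s, "GeneSet")) geneIds(s) else s
      rows[[length(rows) + 1L]] <-
        fisherOverlap(intersect(clusterGenes[[cl]], universe),
                      intersect(genes, universe), universe,
                      nameA = cl, nameB = gs)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- adjustP(out$p, method = correction)
  out
}

#' Pathway enrichment with size filters
#'
#' Filters the pathway collection to sets with between `minSize` and
#' `maxSize` genes inclusive (sets smaller than 50 and larger than 1000
#' are excluded by default), tests each retained set against the query
#' with [fisherOverlap()], applies Benjamini-Hochberg FDR across the
#' retained sets, and flags as significant the results passing both the
#' raw-p and FDR cutoffs (p < 1e-3 and FDR < 0.01 by default).
#'
#' @param querySet character vector (or [GeneSet-class]) of query genes.
#' @param collection named list of pathway gene sets ([GeneSet-class]
#'   objects or character vectors).
#' @param universe background gene vector.
#' @param minSize,maxSize inclusive size bounds (defaults 50 and 1000).
#' @param pCut,fdrCut significance cutoffs (defaults 1e-3 and 0.01).
#' @return data.frame of per-pathway results with `p_adj` (BH) and a
#'   logical `significant` column; zero rows (with a warning) when no set
#'   survives the size filter.
#' @export
pathwayEnrichment <- function(querySet, collection, universe,
                              minSize = 50L, maxSize = 1000L,
                              pCut = 1e-3, fdrCut = 0.01) {
  if (is(querySet, "GeneSet")) querySet <- geneIds(querySet)
  sizes <- vapply(collection, function(s)
    length(if (is(s, "GeneSet")) geneIds(s) else s), integer(1))
  keep <- sizes >= minSize & sizes <= maxSize
  if (!any(keep)) {
    warning("no pathway passes the size filter; empty result")
    return(data.frame())
  }
  out <- batchEnrich(list(query = querySet), collection[keep], universe,
                     correction = "BH")
  out$significant <- out$p < pCut & out$p_adj < fdrCut
  out
}

#' Jaccard index of two sets
#'
#' |intersection| / |union|; two empty sets give 0 by convention.
#'
#' @param setA,setB character vectors (or [GeneSet-class] objects).
#' @return numeric in \[0,1\].
#' @examples
#' jaccard(c("a", "b"), c("b", "c"))
#' @export
jaccard <- function(setA, setB) {
  if (is(setA, "GeneSet")) setA <- geneIds(setA)
  if (is(setB, "GeneSet")) setB <- geneIds(setB)
  u <- length(union(setA, setB))
  if (u == 0L) return(0)
  length(intersect(setA, setB)) / u
}
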