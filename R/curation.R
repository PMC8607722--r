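#' Classify variants into LOF / missense / other
#'
#' A variant is loss of function (LOF) when its effect is nonsense,
#' frameshift or splicing; missense when the effect is missense; anything
#' else (synonymous, noncoding, other) is "other".
#'
#' @param effect character vector of effect calls from the controlled
#'   vocabulary (nonsense, frameshift, splicing, missense, synonymous,
#'   noncoding, other).
#' @return character vector of the same length with values `"LOF"`,
#'   `"missense"` or `"other"`.
#' @examples
#' classifyVariant(c("frameshift", "missense", "synonymous"))
#' @export
classifyVariant <- function(effect) {
  bad <- which(!effect %in% .effectVocab)
  if (length(bad))
    stop(sprintf("unknown effect label(s) at row(s) %s: %s",
                 paste(head(bad, 5), collapse = ", "),
                 paste(unique(effect[bad]), collapse = ", ")))
  out <- rep("other", length(effect))
  out[effect %in% .lofEffects] <- "LOF"
  out[effect == "missense"] <- "missense"
  out
}

.pctRound <- function(x) {
  ## the curated landscape reports 2 decimals, except sub-1% shares to 3
  ifelse(x < 1, round(x, 3), round(x, 2))
}

#' Summarise a curated variant table
#'
#' Counts and percentages of the mutation landscape, on the denominators a
#' curation reports them: inheritance shares over all records; the de novo
#' exonic/splicing share over all records; category (LOF, missense, other
#' coding) shares over the de novo exonic+splicing records.  Percentages
#' are rounded to 2 decimals (3 decimals below 1%).
#'
#' @param variants data.frame with columns `gene`, `effect`,
#'   `inheritance` (see [generateVariantTable()] / [readVariantsTsv()]).
#' @return a list with `n_total`, `counts` (named: de_novo, inherited,
#'   unknown, de_novo_exonic_splicing, lof, missense, other_coding,
#'   lof_nonsense, lof_frameshift, lof_splicing) and `percent` (named:
#'   de_novo, inherited, unknown over all records;
#'   de_novo_exonic_splicing over all records; lof, missense,
#'   other_coding over the de novo exonic+splicing records).
#' @examples
#' v <- data.frame(gene = c("A", "B"), effect = c("nonsense", "missense"),
#'                 inheritance = c("de_novo", "de_novo"))
#' curationSummary(v)$percent[["lof"]]
#' @export
curationSummary <- function(variants) {
  if (nrow(variants) == 0L) {
    warning("empty variant table; returning all-zero summary")
    zero <- setNames(numeric(10), c(
      "de_novo", "inherited", "unknown", "de_novo_exonic_splicing",
      "lof", "missense", "other_coding",
      "lof_nonsense", "lof_frameshift", "lof_splicing"))
    return(list(n_total = 0L, counts = zero,
                percent = zero[1:7]))
  }
  cls <- classifyVariant(variants$effect)
  n <- nrow(variants)
  inhN <- vapply(.inheritanceVocab,
                 function(i) sum(variants$inheritance == i), numeric(1))
  ## de novo variants with a direct protein impact (exonic or splicing)
  dnExonic <- variants$inheritance == "de_novo" &
    variants$effect %in% c("nonsense", "frameshift", "splicing", "missense",
                           "synonymous", "other")
  nDn <- sum(dnExonic)
  catN <- c(
    lof = sum(dnExonic & cls == "LOF"),
    missense = sum(dnExonic & cls == "missense"),
    other_coding = sum(dnExonic & cls == "other"))
  lofSplit <- vapply(.lofEffects, function(e)
    sum(dnExonic & variants$effect == e), numeric(1))
  counts <- c(de_novo = unname(inhN["de_novo"]),
              inherited = unname(inhN["inherited"]),
              unknown = unname(inhN["unknown"]),
              de_novo_exonic_splicing = nDn,
              catN,
              lof_nonsense = unname(lofSplit["nonsense"]),
              lof_frameshift = unname(lofSplit["frameshift"]),
              lof_splicing = unname(lofSplit["splicing"]))
  percent <- c(.pctRound(100 * counts[1:4] / n),
               if (nDn > 0) .pctRound(100 * catN / nDn)
               else setNames(numeric(3), names(catN)))
  list(n_total = n, counts = counts, percent = percent)
}

#' Unique genes hit by de novo LOF variants
#'
#' @param variants a curated variant table.
#' @param name,provenance passed to [geneSet()].
#' @return a [GeneSet-class] of genes with at least one de novo LOF
#'   record.
#' @examples
#' v <- data.frame(gene = c("A", "A", "B"),
#'                 effect = c("nonsense", "splicing", "missense"),
#'                 inheritance = "de_novo")
#' length(geneIds(lofGeneSet(v)))
#' @export
lofGeneSet <- function(variants, name = "dn_lof",
                       provenance = "de novo LOF variant genes") {
  cls <- classifyVariant(variants$effect)
  keep <- cls == "LOF" & variants$inheritance == "de_novo" &
    nzchar(variants$gene)
  geneSet(name, unique(variants$gene[keep]), provenance)
}

#' Recurrently hit gene sets
#'
#' Three gene sets built from de novo records: genes with >= 2 de novo
#' LOF variants, genes with >= 2 de novo missense variants, and genes
#' with >= 2 de novo LOF-or-missense variants (counted jointly).
#'
#' @param variants a curated variant table.
#' @param minRecords minimum number of records for inclusion (default 2).
#' @return named list of three [GeneSet-class] objects: `multi_lof`,
#'   `multi_missense`, `multi_lof_or_missense`.
#' @export
recurrentGeneSets <- function(variants, minRecords = 2L) {
  cls <- classifyVariant(variants$effect)
  dn <- variants$inheritance == "de_novo" & nzchar(variants$gene)
  tallyAtLeast <- function(keep) {
    tab <- table(variants$gene[keep])
    names(tab)[tab >= minRecords]
  }
  list(
    multi_lof = geneSet("multi_lof", tallyAtLeast(dn & cls == "LOF"),
                        "genes with multiple de novo LOF variants"),
    multi_missense = geneSet("multi_missense",
                             tallyAtLeast(dn & cls == "missense"),
                             "genes with multiple de novo missense variants"),
    multi_lof_or_missense = geneSet(
      "multi_lof_or_missense",
      tallyAtLeast(dn & cls %in% c("LOF", "missense")),
      "genes with multiple de novo LOF or missense variants"))
}
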