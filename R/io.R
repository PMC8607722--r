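#' Write / read a count matrix as an MTX triplet
#'
#' The standard exchange layout: `matrix.mtx` (genes x cells sparse
#' MatrixMarket), `features.tsv` (gene ids), `barcodes.tsv` (cell ids)
#' and `cell_meta.tsv` (the colData, with a `cell_id` column).
#'
#' @param sce SingleCellExperiment with a `counts` assay.
#' @param dir output directory (created if needed).
#' @return `writeCountsMtx`: the directory, invisibly.
#'   `readCountsMtx`: a SingleCellExperiment.
#' @export
writeCountsMtx <- function(sce, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(SummarizedExperiment::assay(sce, "counts"),
                      sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(sce), file.path(dir, "features.tsv"))
  writeLines(colnames(sce), file.path(dir, "barcodes.tsv"))
  meta <- as.data.frame(SummarizedExperiment::colData(sce))
  meta <- cbind(cell_id = rownames(meta), meta)
  write.table(meta, file.path(dir, "cell_meta.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname writeCountsMtx
#' @export
readCountsMtx <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  genes <- readLines(file.path(dir, "features.tsv"))
  cells <- readLines(file.path(dir, "barcodes.tsv"))
  dimnames(m) <- list(genes, cells)
  meta <- read.delim(file.path(dir, "cell_meta.tsv"),
                     stringsAsFactors = FALSE)
  rownames(meta) <- meta$cell_id
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m),
    colData = S4Vectors::DataFrame(meta[cells, -1, drop = FALSE]))
}

#' Write / read gene sets in GMT format
#'
#' One set per line: name, description, then the genes, tab-separated.
#'
#' @param sets named list of [GeneSet-class] objects or character
#'   vectors.
#' @param path file path.
#' @return `writeGmt`: the path, invisibly. `readGmt`: a named list of
#'   [GeneSet-class] objects.
#' @export
writeGmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    s <- sets[[nm]]
    genes <- if (is(s, "GeneSet")) geneIds(s) else s
    desc <- if (is(s, "GeneSet")) s@provenance else ""
    if (!nzchar(desc)) desc <- "na"
    paste(c(nm, desc, genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeGmt
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    geneSet(parts[1], parts[-(1:2)],
            provenance = if (parts[2] == "na") "" else parts[2])
  })
  names(sets) <- vapply(sets, setName, character(1))
  sets
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' TSV writers and readers for the pipeline tables
#'
#' Plain tab-separated files with a header row: the variant table
#' (`variant_id`, `gene`, `effect`, `inheritance`, `case_id`), the pLI
#' table (`gene`, `pli`), the exon models (`gene`, `exon_index`,
#' `length_bp`, `nonsyn_count`, `expr_PN`, `expr_EC`, `expr_AD`), the
#' spatiotemporal grid in long format (`gene`, `region`, `period`,
#' `value`) and the sorted-cell reference (`gene`, one column per cell
#' type, optional `detection`).
#'
#' @param x the object to write (see Details per function).
#' @param path file path.
#' @name pipeline-tsv
#' @return writers return the path invisibly; readers return the parsed
#'   object.
NULL

#' @rdname pipeline-tsv
#' @export
writeVariantsTsv <- function(x, path) .writeTsv(x, path)

#' @rdname pipeline-tsv
#' @export
readVariantsTsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = NULL)
  df$gene <- as.character(df$gene)
  df$gene[is.na(df$gene)] <- ""
  df
}

#' @rdname pipeline-tsv
#' @export
writePliTsv <- function(x, path) .writeTsv(x, path)

#' @rdname pipeline-tsv
#' @export
readPliTsv <- function(path) read.delim(path, stringsAsFactors = FALSE)

#' @rdname pipeline-tsv
#' @export
writeExonTsv <- function(x, path) .writeTsv(x, path)

#' @rdname pipeline-tsv
#' @export
readExonTsv <- function(path) read.delim(path, stringsAsFactors = FALSE)

#' @rdname pipeline-tsv
#' @export
writeSpatioTsv <- function(x, path) {
  mat <- SummarizedExperiment::assay(x, "rpkm")
  cd <- SummarizedExperiment::colData(x)
  long <- data.frame(
    gene = rep(rownames(mat), times = ncol(mat)),
    region = rep(cd$region, each = nrow(mat)),
    period = rep(cd$period, each = nrow(mat)),
    value = as.vector(mat), stringsAsFactors = FALSE)
  .writeTsv(long, path)
}

#' @rdname pipeline-tsv
#' @export
readSpatioTsv <- function(path) {
  long <- read.delim(path, stringsAsFactors = FALSE)
  key <- paste(long$region, long$period, sep = ".")
  cols <- unique(key)
  genes <- unique(long$gene)
  mat <- matrix(NA_real_, length(genes), length(cols),
                dimnames = list(genes, cols))
  mat[cbind(match(long$gene, genes), match(key, cols))] <- long$value
  first <- !duplicated(key)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(rpkm = mat),
    colData = S4Vectors::DataFrame(region = long$region[first],
                                   period = long$period[first],
                                   row.names = cols))
}

#' @rdname pipeline-tsv
#' @export
writeSortedTsv <- function(x, path) {
  mat <- SummarizedExperiment::assay(x, 1)
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  rd <- SummarizedExperiment::rowData(x)
  if ("detection" %in% names(rd)) df$detection <- rd$detection
  .writeTsv(df, path)
}

#' @rdname pipeline-tsv
#' @export
readSortedTsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  det <- if ("detection" %in% names(df)) df$detection else NULL
  mat <- as.matrix(df[, setdiff(names(df), c("gene", "detection")),
                      drop = FALSE])
  rownames(mat) <- df$gene
  rd <- if (is.null(det)) NULL
        else S4Vectors::DataFrame(detection = det, row.names = df$gene)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(meanexpr = mat), rowData = rd)
}

#' Write / read the planted ground truth as JSON
#'
#' @param truth a [GroundTruth-class].
#' @param path file path.
#' @return `writeGroundTruthJson`: the path, invisibly.
#'   `readGroundTruthJson`: a [GroundTruth-class].
#' @export
writeGroundTruthJson <- function(truth, path) {
  obj <- list(
    cell_labels = as.list(truth@cellLabels),
    marker_catalog = truth@markerCatalog,
    critical_exon_flags = truth@criticalExonFlags,
    high_pli_genes = truth@highPliGenes,
    enriched_variant_genes = truth@enrichedVariantGenes,
    prenatal_biased_genes = truth@prenatalBiasedGenes)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeGroundTruthJson
#' @export
readGroundTruthJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cef <- as.data.frame(obj$critical_exon_flags)
  if (!nrow(cef))
    cef <- data.frame(gene = character(), exon_index = integer(),
                      stage = character())
  new("GroundTruth",
      cellLabels = unlist(obj$cell_labels),
      markerCatalog = lapply(obj$marker_catalog, as.character),
      criticalExonFlags = cef,
      highPliGenes = as.character(obj$high_pli_genes),
      enrichedVariantGenes = as.character(obj$enriched_variant_genes),
      prenatalBiasedGenes = as.character(obj$prenatal_biased_genes))
}
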