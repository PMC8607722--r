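test_that("generated counts honour sizes, integrality and determinism", {
  cfg <- do.call(synthConfig, smallConfig(seed = 7))
  out <- generateCounts(cfg)
  m <- SummarizedExperiment::assay(out$sce, "counts")
  expect_identical(dim(m), c(600L, 240L))
  expect_true(all(m >= 0) && all(m == round(m)))
  expect_identical(as.vector(table(out$truth@cellLabels)[c("neuron", "astrocyte", "oligodendrocyte")]),
                   c(120L, 60L, 60L))
  # marker sets disjoint
  mk <- unlist(out$truth@markerCatalog)
  expect_false(anyDuplicated(mk) > 0)
  # bit-identical reruns from the same config
  out2 <- generateCounts(cfg)
  expect_identical(SummarizedExperiment::assay(out2$sce, "counts"), m)
  expect_identical(out2$truth@cellLabels, out$truth@cellLabels)
})

test_that("a zero-size cell type is rejected by name", {
  expect_error(do.call(synthConfig,
                       smallConfig(cellTypeSizes = c(neuron = 100L, glia = 0L))),
               "glia")
})

test_that("null marker effect leaves home and other type means equal", {
  out <- generateCounts(do.call(synthConfig,
                                smallConfig(seed = 3, markerLog2Effect = 0)))
  m <- SummarizedExperiment::assay(out$sce, "counts")
  labels <- out$truth@cellLabels[colnames(m)]
  diffs <- unlist(lapply(names(out$truth@markerCatalog), function(ct) {
    mk <- out$truth@markerCatalog[[ct]]
    home <- m[mk, labels == ct, drop = FALSE]
    away <- m[mk, labels != ct, drop = FALSE]
    d <- rowMeans(home) - rowMeans(away)
    se <- sqrt(apply(home, 1, var) / ncol(home) +
               apply(away, 1, var) / ncol(away))
    abs(d) / se
  }))
  # no systematic shift: the bulk of markers within 3 SE of zero
  expect_gt(mean(diffs < 3), 0.95)
})

test_that("planted markers match the analytic NB means and separate types", {
  out <- generateCounts(do.call(synthConfig, smallConfig(
    seed = 5, markerLog2Effect = 2,
    cellTypeSizes = c(neuron = 50L, astrocyte = 50L, oligodendrocyte = 50L))))
  m <- SummarizedExperiment::assay(out$sce, "counts")
  labels <- out$truth@cellLabels[colnames(m)]
  expected <- S4Vectors::metadata(out$sce)$expectedTypeMeans
  sep <- ratioToExp <- c()
  for (ct in names(out$truth@markerCatalog)) {
    mk <- out$truth@markerCatalog[[ct]]
    home <- rowMeans(m[mk, labels == ct, drop = FALSE])
    away <- rowMeans(m[mk, labels != ct, drop = FALSE])
    sep <- c(sep, home > 2 * away)
    ratioToExp <- c(ratioToExp, home / expected[mk, ct])
  }
  expect_gte(mean(sep), 0.95)
  # empirical means track the closed-form NB expectation
  expect_lt(abs(mean(ratioToExp) - 1), 0.1)
})

test_that("variant tables conserve requested category counts exactly", {
  cfg <- do.call(synthConfig, smallConfig(seed = 2))
  vt <- generateVariantTable(cfg, new("GroundTruth"))$variants
  got <- table(paste(vt$inheritance, vt$effect, sep = ":"))
  want <- cfg@variantCategoryCounts
  expect_identical(as.integer(got[names(want)]), unname(want))
  # empty counts map gives an empty table
  e <- generateVariantTable(
    do.call(synthConfig, smallConfig(variantCategoryCounts = integer())),
    new("GroundTruth"))$variants
  expect_identical(nrow(e), 0L)
  expect_true(all(c("variant_id", "gene", "effect", "inheritance",
                    "case_id") %in% names(e)))
})

test_that("category labels outside the vocabulary are rejected", {
  expect_error(do.call(synthConfig, smallConfig(
    variantCategoryCounts = c("de_novo:stopgain" = 5L))),
    "vocabulary")
})

test_that("LOF gene sampling follows the renormalised enrichment weights", {
  cfg <- do.call(synthConfig, smallConfig(
    seed = 9, nGenes = 2000L, nMarkersPerType = 20L,
    enrichmentMultiplier = 10,
    variantCategoryCounts = c("de_novo:nonsense" = 10000L),
    nLofGenes = NA_integer_))
  cnt <- generateCounts(cfg)
  vt <- generateVariantTable(cfg, cnt$truth)
  prog <- cnt$truth@markerCatalog[["astrocyte"]]
  pMarker <- 10 * 20 / (10 * 20 + (2000 - 20))  # renormalised weight mass
  frac <- mean(vt$variants$gene %in% prog)
  ci <- qnorm(0.995) * sqrt(pMarker * (1 - pMarker) / 10000)
  expect_lt(abs(frac - pMarker), ci)
  expect_identical(sort(vt$truth@enrichedVariantGenes),
                   sort(intersect(prog, unique(vt$variants$gene))))
})

test_that("surjective allocation yields the requested unique LOF gene count", {
  cfg <- do.call(synthConfig, smallConfig(
    seed = 4, nGenes = 1200L,
    variantCategoryCounts = c("de_novo:nonsense" = 470L,
                              "de_novo:frameshift" = 414L,
                              "de_novo:splicing" = 203L),
    nLofGenes = 852L))
  vt <- generateVariantTable(cfg, generateCounts(cfg)$truth)
  expect_identical(length(geneIds(lofGeneSet(vt$variants))), 852L)
})

test_that("exon models have positive lengths and plantable critical flags", {
  cfg <- do.call(synthConfig, smallConfig(seed = 6, fracCriticalExons = 0.1))
  ex <- generateExonModels(cfg, new("GroundTruth"))
  expect_true(all(ex$exons$length_bp >= 1))
  expect_true(all(ex$exons$exon_index >= 1))
  expect_true(all(table(ex$exons$gene) <= 20))
  nPlanted <- nrow(ex$truth@criticalExonFlags) / 3
  expect_equal(nPlanted, round(0.1 * nrow(ex$exons)))
})

test_that("with no planted critical exons the quadrant count is at chance", {
  cfg <- do.call(synthConfig, smallConfig(seed = 8, nGenes = 1000L,
                                          fracCriticalExons = 0))
  ex <- generateExonModels(cfg, new("GroundTruth"))
  expect_identical(nrow(ex$truth@criticalExonFlags), 0L)
  # brute-force quadrant scan: high expression x low burden at ~ q_e*q_b rate
  e <- ex$exons
  burden <- e$nonsyn_count / e$length_bp
  inQuad <- e$expr_PN >= quantile(e$expr_PN, 0.75) &
    burden <= quantile(burden, 0.25)
  expect_lt(abs(mean(inQuad) - 0.25 * 0.25),
            4 * sqrt(0.0625 * 0.9375 / nrow(e)))
})

test_that("pLI strata are disjoint around 0.9 and hit the planted fraction", {
  cfg <- do.call(synthConfig, smallConfig(seed = 10, fracHighPli = 0.1))
  cnt <- generateCounts(cfg)
  out <- generatePli(cfg, cnt$truth)
  high <- out$pli$gene[out$pli$pli >= 0.9]
  expect_setequal(high, out$truth@highPliGenes)
  p <- length(high) / nrow(out$pli)
  expect_lt(abs(p - 0.1), 3 * sqrt(0.1 * 0.9 / nrow(out$pli)))
  # zero fraction plants nothing
  none <- generatePli(do.call(synthConfig, smallConfig(fracHighPli = 0)),
                      cnt$truth)
  expect_identical(sum(none$pli$pli >= 0.9), 0L)
})

test_that("the spatiotemporal grid is genes x 48 with planted prenatal bias", {
  syn <- smallStudy(seed = 11)
  st <- syn$spatiotemporal
  expect_identical(dim(SummarizedExperiment::assay(st)), c(600L, 48L))
  cd <- SummarizedExperiment::colData(st)
  expect_identical(nrow(unique(as.data.frame(cd))), 48L)
  # with bias 0, per-gene period means agree within noise
  syn0 <- smallStudy(seed = 11, prenatalBiasLog2 = 0)
  m <- SummarizedExperiment::assay(syn0$spatiotemporal)
  cd0 <- SummarizedExperiment::colData(syn0$spatiotemporal)
  pn <- rowMeans(m[, cd0$period == "prenatal"])
  ad <- rowMeans(m[, cd0$period == "adult"])
  expect_lt(abs(median(log2(pn / ad))), 0.1)
})

test_that("short region lists draw a warning but proceed", {
  cfg <- do.call(synthConfig, smallConfig(regions = c("DFC", "V1C", "AMY")))
  expect_warning(st <- generateSpatiotemporal(cfg, new("GroundTruth")),
                 "16 regions")
  expect_identical(ncol(st$spatiotemporal), 9L)
})

test_that("the sorted-cell reference has the documented column order", {
  syn <- smallStudy(seed = 12)
  expect_identical(colnames(SummarizedExperiment::assay(syn$sorted)),
                   c("neurons", "astrocytes", "oligodendrocytes",
                     "microglia", "OPC"))
  # restriction ratio 1 leaves fold changes near 1
  syn1 <- smallStudy(seed = 12, sortedRestrictionRatio = 1)
  fc <- foldChangeVsNeurons(syn1$sorted)
  expect_lt(abs(median(log2(fc$fc))), 0.2)
})

test_that("identical configs give bit-identical full studies", {
  a <- smallStudy(seed = 21)
  b <- smallStudy(seed = 21)
  expect_identical(SummarizedExperiment::assay(a$sce, "counts"),
                   SummarizedExperiment::assay(b$sce, "counts"))
  expect_identical(a$variants, b$variants)
  expect_identical(a$exons, b$exons)
  expect_identical(a$pli, b$pli)
  expect_identical(SummarizedExperiment::assay(a$spatiotemporal),
                   SummarizedExperiment::assay(b$spatiotemporal))
  expect_identical(SummarizedExperiment::assay(a$sorted),
                   SummarizedExperiment::assay(b$sorted))
})
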