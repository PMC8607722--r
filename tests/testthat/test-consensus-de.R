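test_that("Wilcoxon p is exact by enumeration at small n", {
  expect_equal(deWilcoxon(c(1, 2, 3), c(4, 5, 6)), 0.1)
  # against the enumeration oracle, with and without ties
  cases <- list(
    list(x = c(1, 2, 3), y = c(4, 5, 6)),
    list(x = c(1.5, 2.2, 9), y = c(0.1, 2.3, 4, 5)),
    list(x = c(0, 0, 1, 2), y = c(0, 3, 3, 5)),
    list(x = c(2, 2, 2, 7, 8), y = c(1, 2, 2, 6)))
  for (cs in cases)
    expect_equal(deWilcoxon(cs$x, cs$y), oracleWilcoxP(cs$x, cs$y),
                 info = paste(cs$x, collapse = ","))
  # tie-free small samples agree with the reference implementation
  set.seed(71)
  for (i in 1:5) {
    x <- rnorm(6); y <- rnorm(8)
    expect_equal(deWilcoxon(x, y),
                 wilcox.test(x, y, exact = TRUE)$p.value)
  }
})

test_that("Wilcoxon handles identical and degenerate groups", {
  expect_equal(deWilcoxon(c(1, 2, 3), c(3, 1, 2)), 1)
  expect_equal(deWilcoxon(rep(2, 10), rep(2, 12)), 1)
  expect_error(deWilcoxon(c(1, 2), c(1, 2, 3)), "at least 3")
})

test_that("Welch t equals the closed-form computation", {
  x <- c(1.1, 2.3, 0.7, 1.9); y <- c(2.8, 3.1, 2.2, 4.0)
  s2x <- var(x) / 4; s2y <- var(y) / 4
  tstat <- (mean(x) - mean(y)) / sqrt(s2x + s2y)
  df <- (s2x + s2y)^2 / (s2x^2 / 3 + s2y^2 / 3)
  expect_equal(deTtest(x, y), 2 * pt(-abs(tstat), df), tolerance = 1e-10)
  expect_equal(deTtest(x, x), 1)
  expect_equal(deTtest(rep(1, 5), rep(1, 6)), 1)
  expect_equal(deTtest(rep(1, 5), rep(2, 6)), 0)
})

test_that("bimodal LRT MLEs match the direct likelihood optimiser", {
  set.seed(72)
  x <- c(rep(0, 6), rnorm(8, 3, 0.7))
  y <- c(rep(0, 2), rnorm(4, 4, 0.7))
  fit <- deBimod(x, y, details = TRUE)
  opt <- oracleBimodMle(x, y)
  expect_equal(fit$mle$pi1, opt$pi1, tolerance = 1e-6)
  expect_equal(fit$mle$pi2, opt$pi2, tolerance = 1e-6)
  expect_equal(fit$mle$mu1, opt$mu1, tolerance = 1e-6)
  expect_equal(fit$mle$mu2, opt$mu2, tolerance = 1e-6)
  expect_equal(fit$mle$sigmaA, opt$sigma, tolerance = 1e-6)
})

test_that("bimodal LRT is null on identical structure, powered on detection", {
  set.seed(73)
  base <- c(rep(0, 10), rnorm(15, 2))
  fit <- deBimod(base, base, details = TRUE)
  expect_lt(fit$stat, 1e-8)
  expect_equal(fit$p, 1)
  # detection probability 0.2 vs 0.8, equal positive means
  hits <- replicate(100, {
    x <- ifelse(rbinom(100, 1, 0.2) == 1, rnorm(100, 2, 0.5), 0)
    y <- ifelse(rbinom(100, 1, 0.8) == 1, rnorm(100, 2, 0.5), 0)
    deBimod(x, y) < 0.01
  })
  expect_gte(mean(hits), 0.9)
  # no positives anywhere: reduces to a df = 1 proportion comparison
  fit0 <- deBimod(rep(0, 5), rep(0, 6), details = TRUE)
  expect_identical(fit0$df, 1L)
  expect_equal(fit0$p, 1)
})

test_that("hurdle logistic deviance matches the IRLS oracle", {
  x <- c(0, 0, 0, 1.2, 2.1, 0.8)
  y <- c(0, 2.2, 1.8, 2.5, 0, 3.1)
  fit <- deHurdle(x, y, details = TRUE)
  detect <- as.numeric(c(x, y) > 0)
  X1 <- cbind(1, rep(c(1, 0), c(6, 6)))
  dev1 <- oracleLogisticDeviance(detect, X1)
  dev0 <- oracleLogisticDeviance(detect, X1[, 1, drop = FALSE])
  expect_equal(fit$lr_logistic, dev0 - dev1, tolerance = 1e-8)
})

test_that("hurdle is null when both parts are null, flags separation", {
  set.seed(74)
  base <- c(rep(0, 8), rnorm(12, 3))
  fit <- deHurdle(base, base, details = TRUE)
  expect_gt(fit$p, 0.99)
  # detection-only shift: hurdle fires where the t test on values does not
  x <- c(rep(0, 30), rnorm(10, 2, 0.3))
  y <- c(rep(0, 10), rnorm(30, 2, 0.3))
  expect_lt(deHurdle(x, y), 0.001)
  expect_gt(deTtest(x[x > 0], y[y > 0]), 0.05)
  # complete separation in the detection part is flagged, p stays sane
  xs <- rnorm(8, 5) ; ys <- rep(0, 8)
  p <- deHurdle(xs, ys)
  expect_true(attr(p, "separation"))
  expect_lt(as.numeric(p), 0.01)
})

test_that("multiple-testing adjustment matches Bonferroni and BH step-up", {
  expect_equal(adjustP(0.01, m = 10), 0.1)
  expect_equal(adjustP(0.5, m = 3), 1)
  p <- c(0.01, 0.02, 0.03, 0.9)
  expect_equal(adjustP(p, method = "BH"), oracleBH(p))
  set.seed(75)
  pr <- runif(10)
  expect_equal(adjustP(pr, method = "BH"), oracleBH(pr))
  expect_error(adjustP(c(0.5, 1.2)), "0,1")
})

test_that("two-sided tests are symmetric under group swap", {
  set.seed(76)
  x <- c(rep(0, 5), rnorm(15, 2)); y <- c(rep(0, 10), rnorm(20, 2.5))
  expect_equal(deWilcoxon(x, y), deWilcoxon(y, x))
  expect_equal(deTtest(x, y), deTtest(y, x))
  expect_equal(deBimod(x, y), deBimod(y, x))
  expect_equal(as.numeric(deHurdle(x, y)), as.numeric(deHurdle(y, x)))
})

test_that("consensus keeps only genes significant in all four tests", {
  base <- data.frame(gene = c("A", "B", "C"), cluster = 0L,
                     log2_fc = c(2, 1, 3), pct_in = 1, pct_out = 0.5)
  for (tn in c("wilcox", "t", "bimod", "hurdle")) {
    base[[paste0("p_", tn)]] <- 1e-6
    base[[paste0("p_adj_", tn)]] <- 1e-5
  }
  base$p_adj_hurdle[2] <- 0.5   # B significant in only 3 of 4
  out <- consensusDE(base, threshold = 0.001)
  expect_identical(out[["0"]]$gene, c("C", "A"))  # ordered by fold change
  expect_error(consensusDE(base[, setdiff(names(base), "p_adj_bimod")]),
               "p_adj_bimod")
})

test_that("consensus DE recovers planted markers with low truth-FDR", {
  syn <- smallStudy(seed = 54, cellTypeSizes = c(neuron = 100L,
                                                 astrocyte = 100L,
                                                 oligodendrocyte = 100L))
  pipe <- runClusterPipeline(syn$sce, resolution = 0.8, seed = 1)
  de <- runConsensusDE(pipe$sce, pipe$labeling)
  cons <- consensusDE(de, threshold = 0.001)
  labels <- clusterLabels(pipe$labeling)
  truth <- syn$truth@cellLabels[names(labels)]
  sens <- fdr <- c()
  for (cl in names(cons)) {
    cells <- names(labels)[labels == as.integer(cl)]
    homeType <- names(which.max(table(truth[cells])))
    markers <- syn$truth@markerCatalog[[homeType]]
    up <- cons[[cl]]$gene[cons[[cl]]$log2_fc > 0]
    sens <- c(sens, mean(markers %in% up))
    fdr <- c(fdr, mean(!up %in% markers))
  }
  expect_gte(mean(sens), 0.9)
  expect_lte(mean(fdr), 0.05)
})

test_that("consensus sets are contained in each single-test significant set", {
  syn <- smallStudy(seed = 55)
  pipe <- runClusterPipeline(syn$sce, resolution = 0.8, seed = 1)
  de <- runConsensusDE(pipe$sce, pipe$labeling)
  cons <- consensusDE(de, threshold = 0.001)
  for (cl in names(cons)) {
    sub <- de[de$cluster == as.integer(cl), ]
    for (tn in c("wilcox", "t", "bimod", "hurdle")) {
      single <- sub$gene[sub[[paste0("p_adj_", tn)]] < 0.001]
      expect_true(all(cons[[cl]]$gene %in% single))
    }
  }
})
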