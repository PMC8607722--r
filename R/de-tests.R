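#' Wilcoxon rank-sum test for one-vs-rest expression
#'
#' Two-sided Wilcoxon rank-sum p-value.  When both groups have at most 8
#' observations the p-value is computed by exact enumeration of all rank
#' assignments (tie-safe, via midranks); otherwise the tie-corrected
#' normal approximation (no continuity correction) is used.  A fully tied
#' input returns p = 1.
#'
#' @param x,y numeric expression values of the two groups (each >= 3).
#' @return two-sided p-value.
#' @examples
#' deWilcoxon(c(1, 2, 3), c(4, 5, 6))  # exact: 0.1
#' @export
deWilcoxon <- function(x, y) {
  .checkGroups(x, y)
  if (length(unique(c(x, y))) == 1L) return(1)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  if (n1 <= 8L && n2 <= 8L) {
    cmb <- combn(N, n1)
    Ws <- colSums(matrix(r[cmb], nrow = n1))
    return(mean(abs(Ws - mu) >= abs(W - mu) - 1e-12))
  }
  tab <- table(r)
  tieTerm <- sum(tab^3 - tab)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tieTerm / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  z <- (W - mu) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

.checkGroups <- function(x, y) {
  if (length(x) < 3L || length(y) < 3L)
    stop("each group needs at least 3 cells")
}

#' Welch two-sample t test
#'
#' Two-sided Welch t-test p-value; with zero variance in both groups the
#' p-value is 1 when the means agree and 0 otherwise.
#'
#' @param x,y numeric expression values of the two groups (each >= 3).
#' @return two-sided p-value.
#' @export
deTtest <- function(x, y) {
  .checkGroups(x, y)
  if (var(x) == 0 && var(y) == 0)
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  t.test(x, y, var.equal = FALSE)$p.value
}

.ll_binom <- function(k, n) {
  # maximised Bernoulli log-likelihood, with 0 log 0 = 0
  p <- k / n
  term <- function(a, q) if (a == 0) 0 else a * log(q)
  term(k, p) + term(n - k, 1 - p)
}

#' Bimodal likelihood-ratio test
#'
#' Likelihood-ratio test of a zero-inflated expression model: a point
#' mass at zero with probability `1 - pi` and a normal on the positive
#' values.  The null fits shared `(pi, mu, sigma)` across the two groups;
#' the alternative fits per-group `(pi, mu)` with a shared `sigma`.  The
#' statistic `2 * delta-loglik` is referred to chi-square with df = 2
#' (df = 1 when the positive part is unavailable, e.g. no positive values
#' in a group, in which case the test reduces to the detection-proportion
#' comparison).
#'
#' @param x,y numeric expression values of the two groups (each >= 3).
#' @param details if TRUE, return the statistic, df and fitted MLEs too.
#' @return p-value, or a list when `details = TRUE`.
#' @export
deBimod <- function(x, y, details = FALSE) {
  .checkGroups(x, y)
  n1 <- length(x); n2 <- length(y)
  px <- x[x > 0]; py <- y[y > 0]
  k1 <- length(px); k2 <- length(py)

  statB <- 2 * (.ll_binom(k1, n1) + .ll_binom(k2, n2) -
                .ll_binom(k1 + k2, n1 + n2))

  havePos <- k1 >= 2L && k2 >= 2L
  statN <- 0
  mle <- list(pi1 = k1 / n1, pi2 = k2 / n2, pi0 = (k1 + k2) / (n1 + n2))
  if (havePos) {
    mu1 <- mean(px); mu2 <- mean(py)
    rssA <- sum((px - mu1)^2) + sum((py - mu2)^2)
    allp <- c(px, py)
    mu0 <- mean(allp)
    rss0 <- sum((allp - mu0)^2)
    np <- k1 + k2
    s2A <- rssA / np
    s20 <- rss0 / np
    if (s2A > 0 && s20 > 0) statN <- np * log(s20 / s2A)
    mle <- c(mle, list(mu1 = mu1, mu2 = mu2, mu0 = mu0,
                       sigmaA = sqrt(s2A), sigma0 = sqrt(s20)))
  }
  df <- 1L + as.integer(havePos)
  stat <- max(statB + statN, 0)
  p <- pchisq(stat, df = df, lower.tail = FALSE)
  if (details) list(p = p, stat = stat, df = df, mle = mle) else p
}

#' Two-part hurdle expression test
#'
#' MAST-style hurdle: a logistic regression of detection (value > 0) on
#' group membership and a Gaussian regression of the positive values on
#' group; the two likelihood-ratio chi-square statistics are summed and
#' referred to chi-square with df = 2 (df = 1 when the continuous part is
#' unavailable).  Complete separation in the logistic part (an empty cell
#' in the detection x group table) triggers a penalised fallback -- a
#' Jeffreys-style 0.5 augmentation of the 2x2 table -- and is flagged on
#' the result (`attr(p, "separation")` / `flag` in the details).
#'
#' @param x,y numeric expression values of the two groups (each >= 3).
#' @param covariates optional data.frame of per-cell covariates
#'   (rows: cells of `x` then `y`) entering the logistic part.
#' @param details if TRUE, return the parts and flags too.
#' @return p-value with attribute `separation`, or a list when
#'   `details = TRUE`.
#' @export
deHurdle <- function(x, y, covariates = NULL, details = FALSE) {
  .checkGroups(x, y)
  n1 <- length(x); n2 <- length(y)
  detect <- c(x, y) > 0
  group <- factor(rep(c("in", "out"), c(n1, n2)), levels = c("out", "in"))
  tab <- table(group, detect)
  flag <- FALSE

  if (is.null(covariates)) {
    if (nrow(tab) < 2L || ncol(tab) < 2L || any(tab == 0)) {
      ## quasi/complete separation: Jeffreys-style 0.5-augmented LRT
      flag <- TRUE
      k1 <- sum(x > 0) + 0.5; k2 <- sum(y > 0) + 0.5
      m1 <- n1 + 1; m2 <- n2 + 1
      lr1 <- 2 * (.ll_binomReal(k1, m1) + .ll_binomReal(k2, m2) -
                  .ll_binomReal(k1 + k2, m1 + m2))
    } else {
      lr1 <- 2 * (.ll_binom(sum(x > 0), n1) + .ll_binom(sum(y > 0), n2) -
                  .ll_binom(sum(detect), n1 + n2))
    }
  } else {
    dat <- data.frame(detect = detect, group = group, covariates)
    fit <- suppressWarnings(glm(detect ~ ., data = dat, family = binomial()))
    fit0 <- suppressWarnings(glm(detect ~ . - group, data = dat,
                                 family = binomial()))
    if (any(abs(coef(fit)) > 15, na.rm = TRUE)) flag <- TRUE
    lr1 <- max(fit0$deviance - fit$deviance, 0)
  }

  px <- x[x > 0]; py <- y[y > 0]
  havePos <- length(px) >= 2L && length(py) >= 2L
  lr2 <- 0
  if (havePos) {
    allp <- c(px, py)
    np <- length(allp)
    rss1 <- sum((px - mean(px))^2) + sum((py - mean(py))^2)
    rss0 <- sum((allp - mean(allp))^2)
    if (rss1 > 0 && rss0 > 0) lr2 <- np * log(rss0 / rss1)
  }
  df <- 1L + as.integer(havePos)
  p <- pchisq(max(lr1, 0) + max(lr2, 0), df = df, lower.tail = FALSE)
  if (details)
    return(list(p = p, lr_logistic = lr1, lr_gaussian = lr2, df = df,
                flag = flag))
  attr(p, "separation") <- flag
  p
}

.ll_binomReal <- function(k, n) {
  p <- k / n
  k * log(p) + (n - k) * log(1 - p)
}

#' Multiple-testing adjustment
#'
#' Bonferroni (`min(1, m * p)`) by default; Benjamini-Hochberg is
#' provided for the pathway stage.
#'
#' @param p p-values in \[0,1\].
#' @param method `"bonferroni"` or `"BH"`.
#' @param m number of tests (default `length(p)`; for per-cluster
#'   correction pass the number of genes tested).
#' @return adjusted p-values.
#' @examples
#' adjustP(0.01, m = 10)
#' adjustP(c(0.01, 0.02, 0.03, 0.9), method = "BH")
#' @export
adjustP <- function(p, method = c("bonferroni", "BH"), m = length(p)) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0,1]")
  p.adjust(p, method = method, n = max(m, length(p)))
}
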