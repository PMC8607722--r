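# Independent oracles, deliberately written against the definitions rather
# than the implementation paths they check.

# two-sided rank-sum p by full enumeration of group assignments
oracleWilcoxP <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  sets <- utils::combn(length(r), n1)
  stat <- function(idx) sum(r[idx])
  mu <- n1 * mean(r)
  obs <- abs(stat(seq_len(n1)) - mu)
  devs <- abs(apply(sets, 2, stat) - mu)
  sum(devs >= obs - 1e-12) / ncol(sets)
}

# hypergeometric upper tail by direct summation of dhyper terms
oracleHyperP <- function(overlap, aSize, bSize, universeSize) {
  ks <- overlap:min(aSize, bSize)
  sum(choose(bSize, ks) * choose(universeSize - bSize, aSize - ks)) /
    choose(universeSize, aSize)
}

# zero-inflated normal MLEs by direct numeric likelihood maximisation
oracleBimodMle <- function(x, y) {
  nll <- function(par) {
    # par: qlogis(pi1), qlogis(pi2), mu1, mu2, log(sigma)
    pi1 <- plogis(par[1]); pi2 <- plogis(par[2])
    s <- exp(par[5])
    ll <- sum(log(ifelse(x > 0, pi1 * dnorm(x, par[3], s), 1 - pi1))) +
      sum(log(ifelse(y > 0, pi2 * dnorm(y, par[4], s), 1 - pi2)))
    -ll
  }
  start <- c(0, 0, mean(x[x > 0]), mean(y[y > 0]), log(sd(c(x, y)[c(x, y) > 0])))
  fit <- optim(start, nll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  list(pi1 = plogis(fit$par[1]), pi2 = plogis(fit$par[2]),
       mu1 = fit$par[3], mu2 = fit$par[4], sigma = exp(fit$par[5]),
       nll = fit$value)
}

# logistic regression deviance by hand-rolled IRLS
oracleLogisticDeviance <- function(yBin, X) {
  beta <- rep(0, ncol(X))
  for (i in 1:100) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    z <- eta + (yBin - p) / pmax(W, 1e-12)
    beta <- solve(crossprod(X, X * W), crossprod(X, W * z))
  }
  eta <- drop(X %*% beta)
  p <- 1 / (1 + exp(-eta))
  -2 * sum(yBin * log(p) + (1 - yBin) * log(1 - p))
}

# least-squares residuals from the normal equations
oracleLsResiduals <- function(yVec, X) {
  beta <- solve(crossprod(X), crossprod(X, yVec))
  yVec - drop(X %*% beta)
}

# Benjamini-Hochberg step-up by hand
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
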