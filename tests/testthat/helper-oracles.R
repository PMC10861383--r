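## Independent oracles used to freeze expected values. Each is coded from
## first principles, separately from the package implementation it checks.

## Best 2-partition of the rows of X by total within-cluster sum of squares,
## by exhaustive enumeration of all 2^(n-1) - 1 splits (n <= 12).
bruteForce2Partition <- function(X) {
  n <- nrow(X)
  stopifnot(n <= 12)
  wss <- function(idx) {
    if (length(idx) < 2) return(0)
    sum(scale(X[idx, , drop = FALSE], scale = FALSE)^2)
  }
  best <- NULL
  bestScore <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    inA <- c(TRUE, as.logical(bitwAnd(code, 2^(0:(n - 2)))))
    score <- wss(which(inA)) + wss(which(!inA))
    if (score < bestScore) {
      bestScore <- score
      best <- inA
    }
  }
  ifelse(best, 1L, 2L)
}

## Best rank-1 trilinear approximation by higher-order power iteration.
hopmRank1 <- function(x, iters = 500) {
  d <- dim(x)
  m1 <- matrix(x, d[1], d[2] * d[3])
  u <- svd(m1, nu = 1, nv = 0)$u[, 1]
  v <- rep(1 / sqrt(d[2]), d[2])
  w <- rep(1 / sqrt(d[3]), d[3])
  nrm <- function(z) z / sqrt(sum(z^2))
  for (i in seq_len(iters)) {
    u <- nrm(sapply(seq_len(d[1]), function(a)
      sum(x[a, , ] * outer(v, w))))
    v <- nrm(sapply(seq_len(d[2]), function(b)
      sum(x[, b, ] * outer(u, w))))
    wNew <- sapply(seq_len(d[3]), function(c)
      sum(x[, , c] * outer(u, v)))
    lambda <- sqrt(sum(wNew^2))
    w <- wNew / lambda
  }
  list(u = u, v = v, w = w, lambda = lambda)
}

## ICC(2,1) via the classical two-way ANOVA table from aov(), independently
## of the package's sums-of-squares code path.
iccOracleAov <- function(m) {
  df <- data.frame(
    value = as.vector(m),
    subject = factor(rep(seq_len(nrow(m)), ncol(m))),
    occasion = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  tab <- summary(stats::aov(value ~ subject + occasion, data = df))[[1]]
  msr <- tab["subject", "Mean Sq"]
  msc <- tab["occasion", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  n <- nrow(m)
  k <- ncol(m)
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

## Small default generator configurations for fast tests.
tinyConfig <- function(seed = 1L, ...) {
  args <- list(nSubjects = 20L, nMetabolomeFeatures = 30L, nGenera = 20L,
               nClinicalContinuous = 6L, nClinicalCategorical = 2L,
               seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(simConfig, args)
}

## a ClusterAssignment from a plain label vector, names preserved
assignmentFromLabels <- function(lab, k = max(lab)) {
  if (is.null(names(lab)))
    names(lab) <- sprintf("S%03d", seq_along(lab))
  new("ClusterAssignment",
      labels = stats::setNames(as.integer(lab), names(lab)),
      provenance = list(item = "total", representation = "absolute",
                        method = "kmeans", k = as.integer(k),
                        scaled = FALSE))
}
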