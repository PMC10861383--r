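test_that("imputation is the identity on a complete tensor", {
  cfg <- tinyConfig(seed = 2L, missingRate = 0)
  tens <- simulateProvocationTensor(cfg, simulateTrial(cfg))
  expect_identical(tensorValues(imputeTensor(tens)), tensorValues(tens))
})

test_that("matrix completion recovers masked cells of an exact low-rank unfolding", {
  ## rank-3 subjects x (features, time) structure, 5% masked
  set.seed(4)
  n <- 20; p <- 15; tt <- 8
  U <- matrix(rnorm(n * 3), n)
  V <- matrix(rnorm(p * tt * 3), p * tt)
  M <- U %*% t(V)
  vals <- array(M, dim = c(n, p, tt))
  mask <- array(FALSE, dim = dim(vals))
  mask[sample(length(mask), floor(0.05 * length(mask)))] <- TRUE
  ## keep every fiber partly observed
  stopifnot(!any(apply(mask, c(1, 2), all)))
  masked <- vals; masked[mask] <- NA
  tens <- new("ProvocationTensor", values = masked, mask = mask,
              minutes = provocationMinutes(),
              subjectIds = sprintf("S%03d", 1:n),
              featureIds = sprintf("met_%04d", 1:p), groundTruth = list())
  out <- imputeTensor(tens, rank = 3, tol = 1e-10, maxIter = 500)
  rel <- abs(tensorValues(out)[mask] - vals[mask]) /
    pmax(abs(vals[mask]), 1e-8)
  expect_lt(stats::median(rel), 1e-4)
  expect_lt(max(abs(tensorValues(out)[!mask] - vals[!mask])), 1e-12)
})

test_that("imputation rejects a fully missing fiber and reports non-convergence", {
  vals <- array(rnorm(2 * 2 * 8), dim = c(2, 2, 8))
  mask <- array(FALSE, dim = dim(vals))
  mask[1, 1, ] <- TRUE
  vals[mask] <- NA
  tens <- new("ProvocationTensor", values = vals, mask = mask,
              minutes = provocationMinutes(), subjectIds = c("a", "b"),
              featureIds = c("f1", "f2"), groundTruth = list())
  expect_error(imputeTensor(tens), "fully missing")
})

test_that("preprocessing schemes hit their defining normalizations", {
  cfg <- tinyConfig(seed = 6L, missingRate = 0)
  tens <- simulateProvocationTensor(cfg, simulateTrial(cfg))
  unfoldSd <- function(x) apply(x, 2, function(col) sd(as.vector(col)))
  p1 <- preprocessTensor(tens, "sd_one")
  v1 <- tensorValues(p1)
  sds <- vapply(seq_len(dim(v1)[2]), function(j) sd(as.vector(v1[, j, ])),
                numeric(1))
  expect_true(all(abs(sds - 1) < 1e-9))
  ## idempotence of scheme i
  p11 <- preprocessTensor(p1, "sd_one")
  expect_equal(tensorValues(p11), v1, tolerance = 1e-12)
  p2 <- preprocessTensor(tens, "centered_rms_one")
  v2 <- tensorValues(p2)
  rms <- vapply(seq_len(dim(v2)[2]), function(j)
    sqrt(mean(v2[, j, ]^2)), numeric(1))
  expect_true(all(abs(rms - 1) < 1e-9))
  ## scheme ii centering removes each subject's global average
  centered <- tensorValues(preprocessTensor(tens, "centered_rms_one"))
  ## reconstruct pre-scaling: centering alone should zero subject means
  cfg2 <- tinyConfig(seed = 6L, missingRate = 0)
  raw <- tensorValues(simulateProvocationTensor(cfg2, simulateTrial(cfg2)))
  cen <- raw - array(apply(raw, 1, mean), dim = dim(raw))
  expect_lt(max(abs(apply(cen, 1, mean))), 1e-9)
})

test_that("ALS recovers a noise-free trilinear model exactly", {
  cfg <- tinyConfig(seed = 9L, tensorRank = 2L,
                    noiseSd = list(tensor = 0), missingRate = 0)
  tens <- simulateProvocationTensor(cfg, simulateTrial(cfg))
  m <- parafacALS(tens, 2, seed = 1)
  expect_true(isConverged(m))
  expect_gte(modelFit(m), 0.999)
  gt <- tens@groundTruth
  tc <- tuckerCongruence(m, gt$A, gt$B, gt$D)
  expect_true(all(tc > 0.99))
  ## normalization conventions
  expect_equal(colSums(featureLoadings(m)^2), rep(1, 2), tolerance = 1e-9)
  expect_equal(colSums(timeLoadings(m)^2), rep(1, 2), tolerance = 1e-9)
  D <- timeLoadings(m)
  expect_true(all(D[cbind(apply(abs(D), 2, which.max), 1:2)] > 0))
})

test_that("a single component equals the best rank-1 approximation", {
  cfg <- tinyConfig(seed = 12L, missingRate = 0)
  tens <- simulateProvocationTensor(cfg, simulateTrial(cfg))
  pre <- preprocessTensor(tens, "sd_one")
  m <- parafacALS(pre, 1, seed = 1)
  oracle <- hopmRank1(tensorValues(pre))
  recM <- subjectScores(m)[, 1] %o% featureLoadings(m)[, 1] %o%
    timeLoadings(m)[, 1]
  recO <- (oracle$lambda * oracle$u) %o% oracle$v %o% oracle$w
  sseM <- sum((tensorValues(pre) - recM)^2)
  sseO <- sum((tensorValues(pre) - recO)^2)
  expect_lt(abs(sseM - sseO) / sseO, 1e-6)
})

test_that("duplicated subjects get identical scores", {
  cfg <- simConfig(nSubjects = 8L, nMetabolomeFeatures = 12L, nGenera = 10L,
                   missingRate = 0, seed = 3L)
  tens <- simulateProvocationTensor(cfg, simulateTrial(cfg))
  vals <- tensorValues(tens)
  dup <- vals[rep(1:8, 2), , ]
  tens2 <- new("ProvocationTensor", values = dup,
               mask = array(FALSE, dim = dim(dup)),
               minutes = provocationMinutes(),
               subjectIds = sprintf("S%03d", 1:16),
               featureIds = tens@featureIds, groundTruth = list())
  m <- parafacALS(tens2, 2, seed = 1)
  A <- subjectScores(m)
  expect_equal(A[1:8, ], A[9:16, ], tolerance = 1e-8)
})

test_that("ALS residuals are monotone and fits nest across model sizes", {
  cfg <- tinyConfig(seed = 14L, missingRate = 0.03)
  tens <- imputeTensor(simulateProvocationTensor(cfg, simulateTrial(cfg)))
  pre <- preprocessTensor(tens, "sd_one")
  fits <- numeric(0)
  for (C in 1:4) {
    m <- parafacALS(pre, C, seed = 1)
    expect_true(all(diff(m@sseTrace) <= 1e-9 * sum(tensorValues(pre)^2)),
                info = paste("C =", C))
    fits <- c(fits, modelFit(m))
  }
  expect_true(all(diff(fits) >= -1e-9))
})

test_that("the linkage screen enumerates 11,286 candidate models per approach", {
  g <- enumerateLinkageScreen()
  expect_equal(nrow(g), 11286L)
  expect_equal(sum(2:20), length(unique(paste(g$nComponents, g$component))))
  expect_equal(nrow(enumerateLinkageScreen(componentRange = 2:3)),
               (2 + 3) * 3 * 3 * 6)
})

test_that("linkage results carry eligibility and sane ANOVA outputs", {
  cfg <- simConfig(nSubjects = 40L, nMetabolomeFeatures = 30L,
                   nGenera = 15L, missingRate = 0, seed = 8L)
  ds <- simulateTrial(cfg)
  tens <- simulateProvocationTensor(cfg, ds)
  pre <- preprocessTensor(tens, "sd_one")
  models <- lapply(2:3, function(C) parafacALS(pre, C, seed = 1))
  link <- linkageScreen(models, ds, "hierarchical", scaled = TRUE)
  expect_equal(nrow(link), (2 + 3) * 3 * 3 * 6)
  ok <- link[link$eligible & !is.na(link$p), ]
  expect_true(all(ok$p >= 0 & ok$p <= 1))
  expect_true(all(link$minSize[link$eligible] >= 8))
})

test_that("null linkage p-values are calibrated", {
  ## within one dataset the grid's p-values share responses and labels, so
  ## uniformity is judged across independent null replicates (one weakly
  ## dependent draw each) plus a marginal-rate check within a dataset
  ps <- vapply(1:30, function(i) {
    cfg <- simConfig(nSubjects = 40L, nMetabolomeFeatures = 15L,
                     nGenera = 10L, missingRate = 0, seed = 800L + i)
    ds <- simulateTrial(cfg)
    pre <- preprocessTensor(simulateProvocationTensor(cfg, ds), "sd_one")
    m <- parafacALS(pre, 2, seed = 1)
    link <- linkageScreen(list(m), ds, "hierarchical", scaled = TRUE,
                          kValues = 2L)
    ok <- link[link$eligible & link$arm == "FODMAP" & link$item == "total", ]
    if (nrow(ok)) ok$p[1] else NA_real_
  }, numeric(1))
  ps <- ps[!is.na(ps)]
  expect_gt(length(ps), 20L)
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)

  cfg <- simConfig(nSubjects = 74L, nMetabolomeFeatures = 40L,
                   nGenera = 15L, missingRate = 0, seed = 31L)
  ds <- simulateTrial(cfg)
  pre <- preprocessTensor(simulateProvocationTensor(cfg, ds), "sd_one")
  models <- lapply(2:4, function(C) parafacALS(pre, C, seed = 1))
  link <- linkageScreen(models, ds, "kmeans", scaled = TRUE)
  p <- link$p[link$eligible & !is.na(link$p)]
  expect_gt(length(p), 200L)
  expect_lt(mean(p < 0.05), 0.2)
})

test_that("enrichment summary counts per arm and tests homogeneity", {
  mk <- function(counts, nPerArm = 150) {
    do.call(rbind, lapply(seq_along(trialArms()), function(i) {
      sig <- counts[i]
      data.frame(arm = trialArms()[i], eligible = TRUE,
                 p = c(runif(sig, 0, 0.049), runif(nPerArm - sig, 0.06, 1)))
    }))
  }
  set.seed(1)
  res <- mk(c(87, 71, 109), nPerArm = 150)
  enr <- enrichmentSummary(res)
  expect_equal(unname(enr$counts), c(87, 71, 109))
  expect_equal(enr$total, 267)
  ## equal counts give a zero homogeneity statistic
  enr2 <- enrichmentSummary(mk(c(10, 10, 10), nPerArm = 20))
  expect_equal(enr2$homogeneity$statistic, 0)
  expect_equal(enr2$homogeneity$p, 1)
  ## nothing significant
  none <- data.frame(arm = rep(trialArms(), each = 3), eligible = TRUE,
                     p = rep(0.5, 9))
  expect_equal(unname(enrichmentSummary(none)$counts), c(0, 0, 0))
})

test_that("stability screening matches the generating temporal fraction", {
  ## 79% of features vary mostly within subject over time; the rest carry a
  ## dominant stable between-subject signal
  set.seed(44)
  n <- 60; p <- 200; tt <- 8
  unstable <- seq_len(round(0.79 * p))
  vals <- array(rnorm(n * p * tt), dim = c(n, p, tt))
  for (j in setdiff(seq_len(p), unstable))
    vals[, j, ] <- vals[, j, ] + matrix(rnorm(n, sd = 3), n, tt)
  tens <- new("ProvocationTensor", values = exp(vals / 3),
              mask = array(FALSE, dim = dim(vals)),
              minutes = provocationMinutes(),
              subjectIds = sprintf("S%03d", 1:n),
              featureIds = sprintf("met_%04d", 1:p), groundTruth = list())
  icc <- metaboliteStability(tens, log = TRUE)
  frac <- mean(icc < 0.5)
  expect_lt(abs(frac - 0.79), 3 * sqrt(0.79 * 0.21 / p) + 0.02)
})
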