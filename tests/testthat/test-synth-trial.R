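test_that("identical seed and config give a byte-identical dataset", {
  d1 <- simulateTrial(tinyConfig(seed = 42L))
  d2 <- simulateTrial(tinyConfig(seed = 42L))
  expect_identical(sssScores(d1), sssScores(d2))
  for (b in blockNames(d1))
    expect_identical(baselineBlock(d1, b), baselineBlock(d2, b))
  expect_identical(clinicalData(d1), clinicalData(d2))
  expect_identical(trueClass(d1), trueClass(d2))
})

test_that("blocks draw from isolated RNG streams", {
  d1 <- simulateTrial(tinyConfig(seed = 7L))
  d2 <- simulateTrial(tinyConfig(seed = 7L, nMetabolomeFeatures = 200L))
  expect_identical(baselineBlock(d1, "microbiota"),
                   baselineBlock(d2, "microbiota"))
  expect_identical(sssScores(d1), sssScores(d2))
  d3 <- simulateTrial(tinyConfig(seed = 8L))
  expect_false(identical(baselineBlock(d1, "metabolome"),
                         baselineBlock(d3, "metabolome")))
})

test_that("dataset invariants hold: item bounds, closure, complete crossover", {
  ds <- simulateTrial(tinyConfig(seed = 3L))
  arr <- sssScores(ds)
  expect_true(all(arr >= 0 & arr <= 100))
  expect_equal(dim(arr), c(20L, 3L, 2L, 5L))
  rel <- baselineBlock(ds, "microbiota")
  expect_true(all(abs(rowSums(rel) - 1) < 1e-9))
  expect_true(all(baselineBlock(ds, "metabolome") > 0))
})

test_that("global-null mode gives equal arm means and exchangeable blocks", {
  cfg <- simConfig(nSubjects = 500L, nMetabolomeFeatures = 20L,
                   nGenera = 20L, seed = 21L)
  ds <- simulateTrial(cfg)
  tot <- responseValues(condenseResponseFrame(ds, "total", "absolute"))
  expect_gt(t.test(tot[, "FODMAP"], tot[, "placebo"])$p.value, 0.01)
  expect_gt(t.test(tot[, "gluten"], tot[, "placebo"])$p.value, 0.01)
  ## exchangeability: a random subject split shows no distribution shift
  met <- log(baselineBlock(ds, "metabolome")[, 1])
  half <- seq_len(250L)
  expect_gt(suppressWarnings(ks.test(met[half], met[-half])$p.value), 0.01)
})

test_that("a planted FODMAP total-score shift is recovered in the data", {
  ## +60 points for class 2 in the FODMAP arm; occasion noise chosen so the
  ## within-class sd of (intervention - washout) is 30 points
  cfg <- simConfig(nSubjects = 200L, nMetabolomeFeatures = 20L,
                   nGenera = 20L, nClasses = 2L,
                   responseShift = matrix(c(0, 0, 0, 60, 0, 0), 2, 3,
                                          byrow = TRUE),
                   noiseSd = list(sss = 30 / sqrt(2)), seed = 11L)
  ds <- simulateTrial(cfg)
  d <- responseValues(condenseResponseFrame(ds, "total", "difference"))
  cl <- trueClass(ds)
  mdiff <- diff(tapply(d[, "FODMAP"], cl, mean))
  se <- sqrt(sum(tapply(d[, "FODMAP"], cl, var) / table(cl)))
  expect_lt(abs(mdiff - 60), 2 * se)
  ## other arms stay null
  expect_gt(t.test(d[cl == 1, "gluten"], d[cl == 2, "gluten"])$p.value, 0.01)
})

test_that("a planted molecular shift lands on the configured features only", {
  cfg <- tinyConfig(seed = 5L, nClasses = 2L,
                    molecularShift = list(list(block = "metabolome",
                                               features = 1:3,
                                               d = c(0, 2))))
  ds <- simulateTrial(cfg)
  met <- log(baselineBlock(ds, "metabolome"))
  cl <- trueClass(ds)
  gap <- colMeans(met[cl == 2, , drop = FALSE]) -
    colMeans(met[cl == 1, , drop = FALSE])
  expect_true(all(gap[1:3] > 1))
  expect_true(all(abs(gap[-(1:3)]) < 1.5))
  expect_error(
    simulateTrial(tinyConfig(nClasses = 2L, molecularShift = list(
      list(block = "metabolome", features = 999L, d = c(0, 1))))),
    "out of range")
})

test_that("noise-free tensor equals the sum of its planted rank-1 terms", {
  cfg <- tinyConfig(seed = 9L, tensorRank = 2L,
                    noiseSd = list(tensor = 0), missingRate = 0)
  tens <- simulateProvocationTensor(cfg, simulateTrial(cfg))
  gt <- tens@groundTruth
  rec <- array(0, dim = dim(tensorValues(tens)))
  for (r in 1:2)
    rec <- rec + outer(outer(gt$A[, r], gt$B[, r]), gt$D[, r])
  expect_equal(tensorValues(tens), rec, tolerance = 1e-12)
  expect_equal(sum(missingMask(tens)), 0L)
})

test_that("the mask holds exactly the configured number of cells", {
  cfg <- tinyConfig(seed = 13L, missingRate = 0.05)
  tens <- simulateProvocationTensor(cfg, simulateTrial(cfg))
  expect_equal(sum(missingMask(tens)),
               floor(0.05 * 20 * 30 * 8))
  expect_true(all(is.na(tensorValues(tens)[missingMask(tens)])))
})

test_that("a mask leaving a fiber fully missing is rejected", {
  cfg <- simConfig(nSubjects = 5L, nMetabolomeFeatures = 5L, nGenera = 10L,
                   missingRate = 0.99, seed = 1L)
  ds <- simulateTrial(cfg)
  expect_error(simulateProvocationTensor(cfg, ds), "fully missing")
})

test_that("written files round-trip the symptom scores", {
  ds <- simulateTrial(tinyConfig(seed = 17L))
  dir <- withr::local_tempdir()
  paths <- writeTrialDataset(ds, dir)
  expect_true(all(file.exists(paths)))
  long <- read.delim(file.path(dir, "ibs_sss_long.tsv"))
  arr <- sssArrayFromLong(long)
  expect_equal(arr, sssScores(ds), tolerance = 1e-12)
  tens <- simulateProvocationTensor(tinyConfig(seed = 17L), ds)
  tpaths <- writeProvocationTensor(tens, dir)
  expect_true(all(file.exists(tpaths)))
  obs <- read.delim(file.path(dir, "provocation_tensor.tsv"))
  expect_equal(nrow(obs), sum(!missingMask(tens)))
})
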