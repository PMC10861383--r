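test_that("ICC(2,1) matches an independent ANOVA decomposition", {
  m <- matrix(c(9, 2, 5, 8,
                6, 1, 3, 2,
                8, 4, 6, 7), 4, 3)
  expect_equal(icc21(m), iccOracleAov(m), tolerance = 1e-10)
  set.seed(2)
  for (i in 1:5) {
    mm <- matrix(rnorm(8 * 4, sd = 2), 8, 4)
    expect_equal(icc21(mm), iccOracleAov(mm), tolerance = 1e-10)
  }
})

test_that("ICC boundary and null behaviour", {
  m <- cbind(1:6, 1:6, 1:6)       # identical occasions, real subject spread
  expect_equal(icc21(m), 1)
  set.seed(3)
  noise <- matrix(rnorm(200 * 8), 200, 8)
  expect_lt(abs(icc21(noise)), 0.05)
  expect_error(icc21(matrix(5, 4, 3)), "zero total variance")
  expect_error(icc21(matrix(1:3, 1, 3)), "at least 2")
  ## invariance under a global affine transform
  mm <- matrix(rnorm(40), 10, 4)
  expect_equal(icc21(mm), icc21(3 * mm + 7), tolerance = 1e-12)
})

test_that("one-way ANOVA reproduces hand-computed sums of squares", {
  ## groups (1,2,3) vs (4,5,6): SSB = 13.5, SSW = 4, df = (1, 4)
  ft <- onewayAnova(c(1, 2, 3, 4, 5, 6), rep(1:2, each = 3))
  expect_equal(ft$F, 13.5, tolerance = 1e-12)
  expect_equal(ft$p, pf(13.5, 1, 4, lower.tail = FALSE), tolerance = 1e-12)
  ## identical group means, positive within-variance: tiny F, large p
  set.seed(4)
  v <- c(1, 2, 3, 1, 2, 3)
  ft2 <- onewayAnova(v, rep(1:2, each = 3))
  expect_equal(ft2$F, 0, tolerance = 1e-12)
  expect_error(onewayAnova(1:4, c(1, 1, 1, 2)), "at least two observations")
  expect_error(onewayAnova(1:4, rep(1, 4)), "two groups")
})

test_that("ANOVA p-values are uniform under label permutation", {
  set.seed(5)
  v <- rnorm(30)
  g <- rep(1:3, each = 10)
  p <- replicate(1000, onewayAnova(v, sample(g))$p)
  expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 0.01)
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  expect_equal(fisherExact(matrix(c(3, 1, 1, 3), 2)), 34 / 70,
               tolerance = 1e-12)
  expect_equal(fisherExact(matrix(c(5, 0, 0, 5), 2)), 2 / 252,
               tolerance = 1e-12)
  ## transpose symmetry
  tb <- matrix(c(7, 2, 3, 9, 4, 1), 2, 3)
  expect_equal(fisherExact(tb), fisherExact(t(tb)), tolerance = 1e-12)
  ## Monte-Carlo path: deterministic under the seed, valid p
  big <- matrix(rpois(12, 40) + 1, 3, 4)
  p1 <- fisherExact(big, mcCutoff = 10, seed = 9)
  p2 <- fisherExact(big, mcCutoff = 10, seed = 9)
  expect_identical(p1, p2)
  expect_true(p1 > 0 && p1 <= 1)
  expect_error(fisherExact(matrix(c(0, 0, 1, 2), 2)), "margins")
  expect_error(fisherExact(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("BH adjustment reproduces the step-up computation", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(0.37), 0.37)
  expect_equal(bhFdr(rep(1, 5)), rep(1, 5))
  ## never below the raw p, order preserved, monotone in ranks
  set.seed(6)
  p <- runif(50)
  adj <- bhFdr(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_error(bhFdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("cluster characterization finds planted associations and stays calibrated", {
  set.seed(7)
  n <- 40
  lab <- rep(1:2, each = n / 2)
  names(lab) <- sprintf("S%03d", seq_len(n))
  asg <- assignmentFromLabels(lab)
  base <- data.frame(
    planted = lab + rnorm(n, sd = 0.01),
    matrix(rnorm(n * 30), n, dimnames = list(NULL, sprintf("null_%02d", 1:30))),
    cat_null = factor(sample(c("A", "B"), n, replace = TRUE)),
    cat_single = factor(rep("A", n)))
  rownames(base) <- names(lab)
  res <- suppressWarnings(characterizeClusters(asg, base))
  expect_false("cat_single" %in% res$variable)
  expect_true(res$significant[res$variable == "planted"])
  expect_lt(res$p_adj[res$variable == "planted"], 0.05)
  ## null variables essentially never pass after adjustment
  expect_lte(sum(res$significant), 1L)
  expect_equal(res$test[res$variable == "cat_null"], "fisher")
})

test_that("shuffled labels keep the false-positive fraction at the nominal level", {
  set.seed(8)
  n <- 50
  hits <- replicate(20, {
    lab <- sample(rep(1:2, each = n / 2))
    names(lab) <- sprintf("S%03d", seq_len(n))
    asg <- assignmentFromLabels(lab)
    base <- data.frame(x = rnorm(n),
                       y = factor(sample(c("A", "B"), n, replace = TRUE)))
    rownames(base) <- names(lab)
    sum(characterizeClusters(asg, base)$significant)
  })
  expect_lte(mean(hits > 0), 0.15)
})
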