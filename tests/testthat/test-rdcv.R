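test_that("a signal-dominant regression tracks the replicate oracle", {
  ## y is an exact linear function of 3 of 200 predictors plus 1% noise;
  ## the oracle is a forest given only the true variables, scored on an
  ## independent replicate of the same design
  set.seed(42)
  gen <- function(n, p = 200) {
    X <- matrix(rnorm(n * p), n, dimnames = list(NULL, sprintf("V%d", 1:p)))
    sig <- X[, 1] + 2 * X[, 2] - 1.5 * X[, 3]
    list(X = X, y = sig + rnorm(n, 0, 0.01 * sd(sig)))
  }
  tr <- gen(74)
  te <- gen(500)
  fit <- ranger::ranger(x = as.data.frame(tr$X[, 1:3]), y = tr$y,
                        num.trees = 1000, seed = 1, num.threads = 1)
  pr <- predict(fit, data = as.data.frame(te$X[, 1:3]))$predictions
  oracleR2 <- 1 - sum((te$y - pr)^2) / sum((te$y - mean(te$y))^2)
  res <- rdcvFit(tr$X, tr$y,
                 rdcvParams(nRep = 1, nTrees = 300, varSel = TRUE, seed = 3),
                 "regression")
  expect_gt(oracleR2, 0.8)
  expect_gt(fitness(res), 0.6)
  expect_gt(fitness(res), oracleR2 - 0.15)
  ## the elimination ladder homes in on a handful of variables
  expect_lte(selectedVariables(res)$nMid, 10L)
  expect_true(all(c("V1", "V2") %in% selectedVariables(res)$variables))
})

test_that("null responses stay under the a priori Q2 filter", {
  set.seed(7)
  X <- matrix(rnorm(74 * 50), 74, dimnames = list(NULL, sprintf("V%d", 1:50)))
  y <- X[, 1] + rnorm(74, 0, 0.5)
  pp <- rdcvParams(nRep = 1, nOuter = 6, nTrees = 100, varSel = FALSE,
                   seed = 1)
  q2null <- vapply(1:20, function(i) {
    yb <- sample(y)
    pb <- pp; pb@seed <- as.integer(i)
    fitness(rdcvFit(X, yb, pb, "regression"))
  }, numeric(1))
  expect_gte(sum(q2null <= 0.2), 19L)
})

test_that("an uninformative predictor yields chance-level classification", {
  set.seed(5)
  X <- matrix(1, 40, 1, dimnames = list(NULL, "flat"))
  y <- factor(rep(1:2, each = 20))
  res <- rdcvFit(X, y, rdcvParams(nRep = 2, nTrees = 100, varSel = FALSE,
                                  seed = 2), "classification")
  expect_lt(abs(fitness(res) - 0.5), 0.25)
  ## permuted labels converge to 1/k at larger n
  set.seed(6)
  X2 <- matrix(rnorm(200 * 10), 200,
               dimnames = list(NULL, sprintf("V%d", 1:10)))
  y2 <- factor(sample(rep(1:2, each = 100)))
  res2 <- rdcvFit(X2, y2, rdcvParams(nRep = 1, nTrees = 100, varSel = FALSE,
                                     seed = 3), "classification")
  expect_lt(abs(fitness(res2) - 0.5), 0.12)
})

test_that("degenerate responses are rejected", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(rdcvFit(X, rep(1, 10), rdcvParams(), "regression"),
               "constant")
  expect_error(rdcvFit(X, rep("x", 10), rdcvParams(), "classification"),
               "two classes")
  X[1, 1] <- NA
  expect_error(rdcvFit(X, rnorm(10), rdcvParams(), "regression"), "missing")
})

test_that("out-of-fold predictions cover every subject once per repetition", {
  set.seed(8)
  X <- matrix(rnorm(30 * 5), 30, dimnames = list(NULL, paste0("V", 1:5)))
  y <- rnorm(30)
  res <- rdcvFit(X, y, rdcvParams(nRep = 3, nOuter = 5, nTrees = 50,
                                  varSel = FALSE, seed = 1), "regression")
  expect_false(anyNA(res@outOfFold))
  expect_equal(dim(res@outOfFold), c(30L, 3L))
  expect_equal(fitness(res), mean(perRepetitionFitness(res)))
})

test_that("Q2 is invariant to affine rescaling of the predictors", {
  set.seed(9)
  X <- matrix(rnorm(40 * 8), 40, dimnames = list(NULL, paste0("V", 1:8)))
  y <- X[, 1] - X[, 2] + rnorm(40, 0, 0.3)
  pp <- rdcvParams(nRep = 1, nTrees = 100, varSel = FALSE, seed = 4)
  q1 <- fitness(rdcvFit(X, y, pp, "regression"))
  q2 <- fitness(rdcvFit(3 * X + 100, y, pp, "regression"))
  expect_equal(q1, q2, tolerance = 1e-10)
})

test_that("with selection off and n outer segments the screen is LOO", {
  set.seed(11)
  n <- 12
  X <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("V", 1:5)))
  y <- X[, 1] + 0.5 * X[, 2] + rnorm(n, 0, 0.2)
  res <- rdcvFit(X, y, rdcvParams(nRep = 1, nOuter = n, nTrees = 500,
                                  varSel = FALSE, seed = 2), "regression")
  ## every outer segment holds exactly one subject
  loo <- vapply(seq_len(n), function(i) {
    f <- ranger::ranger(x = as.data.frame(X[-i, , drop = FALSE]), y = y[-i],
                        num.trees = 500, seed = 100 + i, num.threads = 1)
    predict(f, data = as.data.frame(X[i, , drop = FALSE]))$predictions
  }, numeric(1))
  q2loo <- 1 - sum((y - loo)^2) / sum((y - mean(y))^2)
  expect_lt(abs(fitness(res) - q2loo), 0.15)
})

test_that("the permutation p uses the plus-one estimator", {
  ## a cleanly separable two-class signal beats every permutation, forcing
  ## p to its lower bound 1/(nPerm + 1)
  set.seed(12)
  n <- 30
  y <- factor(rep(1:2, each = n / 2))
  X <- matrix(rnorm(n * 10), n, dimnames = list(NULL, paste0("V", 1:10)))
  X[, 1] <- X[, 1] + ifelse(y == 2, 6, 0)
  pp <- rdcvParams(nRep = 1, nTrees = 100, varSel = FALSE, seed = 3)
  pt <- permutationTest(X, y, pp, "classification", nPerm = 19)
  expect_equal(pt$observed, 1)
  expect_equal(pt$p, 1 / 20)
  expect_error(permutationTest(X, y, pp, "classification", nPerm = 0),
               "nPerm")
})

test_that("the re-run protocol reports mean and sd over fresh downsamples", {
  set.seed(13)
  lab <- rep(1:2, c(14, 10))
  names(lab) <- sprintf("S%03d", seq_along(lab))
  asg <- assignmentFromLabels(lab)
  X <- matrix(rnorm(24 * 5), 24, dimnames = list(names(lab), paste0("V", 1:5)))
  X[, 1] <- X[, 1] + ifelse(lab == 2, 8, 0)   # perfectly separable
  pp <- rdcvParams(nRep = 1, nTrees = 100, varSel = FALSE, seed = 5)
  rr <- rerunProtocol(X, asg, pp, nReruns = 3)
  expect_equal(rr$meanCR, 1)
  expect_equal(rr$sdCR, 0)
  rr1 <- rerunProtocol(X, asg, pp, nReruns = 1)
  expect_equal(rr1$sdCR, 0)
  bad <- assignmentFromLabels(stats::setNames(rep(1:2, c(20, 4)),
                                              names(lab)))
  expect_error(rerunProtocol(X, bad, pp), "minimum-cluster-size")
})

test_that("screen enumerations reproduce the protocol counts", {
  expect_equal(nrow(enumerateBaselineScreens("regression")), 270L)
  expect_equal(nrow(enumerateBaselineScreens("classification")), 864L)
  reg <- enumerateBaselineScreens("regression")
  expect_equal(sum(reg$arm == "FODMAP"), 90L)
  expect_equal(nrow(unique(reg)), 270L)
  expect_equal(nrow(enumerateProvocationScreens()), 69L)
})
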