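#' @include clustering.R
NULL

#' RdcvParams: settings of the repeated double cross-validation
#'
#' @slot nRep repetitions of the whole double-CV (default 5).
#' @slot nOuter outer segments (default 6).
#' @slot nInner inner segments for the elimination ladder (default 5).
#' @slot nTrees trees per random forest (default 300).
#' @slot keepRatio fraction of variables kept per elimination step
#'   (default 0.75).
#' @slot varSel run the recursive variable-elimination ladder? (default
#'   `TRUE`; off, each outer model uses all variables).
#' @slot seed RNG seed governing segmentation and forests.
#' @seealso [rdcvParams()], [rdcvFit()]
#' @export
setClass("RdcvParams",
  representation(
    nRep      = "integer",
    nOuter    = "integer",
    nInner    = "integer",
    nTrees    = "integer",
    keepRatio = "numeric",
    varSel    = "logical",
    seed      = "integer"
  )
)

setValidity("RdcvParams", function(object) {
  msg <- character()
  if (object@nOuter < 2L || object@nInner < 2L)
    msg <- c(msg, "nOuter and nInner must be at least 2")
  if (object@keepRatio <= 0 || object@keepRatio >= 1)
    msg <- c(msg, "keepRatio must lie strictly between 0 and 1")
  if (object@nRep < 1L || object@nTrees < 1L)
    msg <- c(msg, "nRep and nTrees must be positive")
  if (length(msg)) msg else TRUE
})

#' Build rdCV settings
#'
#' @param nRep,nOuter,nInner,nTrees,keepRatio,varSel,seed see
#'   [RdcvParams-class].
#' @return A validated [RdcvParams-class].
#' @export
rdcvParams <- function(nRep = 5L, nOuter = 6L, nInner = 5L, nTrees = 300L,
                       keepRatio = 0.75, varSel = TRUE, seed = 1L) {
  methods::new("RdcvParams", nRep = as.integer(nRep),
               nOuter = as.integer(nOuter), nInner = as.integer(nInner),
               nTrees = as.integer(nTrees), keepRatio = as.numeric(keepRatio),
               varSel = as.logical(varSel), seed = as.integer(seed))
}

## Fold ids 1..nFold; stratified by class for factors so folds stay balanced.
.makeFolds <- function(y, nFold) {
  n <- length(y)
  fold <- integer(n)
  if (is.factor(y)) {
    for (g in levels(y)) {
      idx <- which(y == g)
      fold[idx] <- sample(rep_len(seq_len(nFold), length(idx)))
    }
  } else {
    fold <- sample(rep_len(seq_len(nFold), n))
  }
  fold
}

.fitRf <- function(X, y, nTrees, importance = "none", seed) {
  ranger::ranger(x = as.data.frame(X), y = y, num.trees = nTrees,
                 importance = importance, num.threads = 1L,
                 seed = as.integer(seed %% 2147483647))
}

.predRf <- function(fit, X) {
  stats::predict(fit, data = as.data.frame(X))$predictions
}

.predError <- function(y, pred) {
  if (is.factor(y)) mean(pred != y) else mean((as.numeric(pred) - y)^2)
}

## Recursive variable-elimination ladder on one outer-training set.
## Returns the per-step inner validation error and the ranked variable sets.
.eliminationLadder <- function(X, y, params, seedBase) {
  vars <- colnames(X)
  steps <- list()
  s <- 0L
  repeat {
    s <- s + 1L
    fold <- .makeFolds(y, params@nInner)
    errs <- numeric(params@nInner)
    imps <- matrix(0, length(vars), params@nInner,
                   dimnames = list(vars, NULL))
    for (f in seq_len(params@nInner)) {
      tr <- fold != f
      fit <- .fitRf(X[tr, vars, drop = FALSE], y[tr], params@nTrees,
                    importance = "permutation",
                    seed = seedBase + 31L * s + f)
      errs[f] <- .predError(y[!tr], .predRf(fit, X[!tr, vars, drop = FALSE]))
      imps[, f] <- fit$variable.importance[vars]
    }
    steps[[s]] <- list(nVar = length(vars), err = mean(errs), vars = vars)
    if (length(vars) <= 2L) break
    keep <- min(length(vars) - 1L, ceiling(params@keepRatio * length(vars)))
    vars <- names(sort(rowMeans(imps), decreasing = TRUE))[seq_len(keep)]
  }
  steps
}

## Min/mid/max optimal variable counts from a ladder: every step whose inner
## error is within 5% of the error range of the minimum counts as optimal;
## mid = rounded geometric mean of the smallest and largest optimal counts.
.ladderOptimum <- function(steps) {
  err <- vapply(steps, `[[`, numeric(1), "err")
  nv <- vapply(steps, `[[`, numeric(1), "nVar")
  tol <- 0.05 * (max(err) - min(err))
  opt <- which(err <= min(err) + tol)
  nMin <- min(nv[opt]); nMax <- max(nv[opt])
  nMid <- max(1, round(sqrt(nMin * nMax)))
  ## variable set at the smallest ladder step still covering nMid variables
  cover <- which(nv >= nMid)
  vset <- steps[[cover[which.min(nv[cover])]]]$vars
  list(nMin = nMin, nMid = nMid, nMax = nMax, vars = vset)
}

#' Repeated double cross-validated random-forest screen
#'
#' The core screening model: in each repetition, subjects are split into
#' `nOuter` outer segments; for each held-out segment a recursive
#' variable-elimination ladder is run on the remaining data (variables
#' ranked by mean out-of-bag permutation importance across `nInner` inner
#' fits, a `keepRatio` fraction kept per step), the variable count
#' minimizing inner validation error is located, and a forest with the
#' "mid" count (rounded geometric mean of the smallest and largest
#' inner-optimal counts) predicts the hold-out. Fitness is computed from
#' the pooled out-of-fold predictions of each repetition — Q2 for
#' regression, classification rate (CR) for classification — and reported
#' as the mean over repetitions. The a priori screen filters are Q2 > 0.2
#' and CR > 0.6.
#'
#' @param X numeric matrix, subjects x features (no missing values; see
#'   [imputeMedian()]).
#' @param y numeric response (regression) or factor/vector of class labels
#'   (classification; balance classes first via [downsampleBalanced()]).
#' @param params an [RdcvParams-class].
#' @param task `regression` or `classification`.
#' @return An [RdcvResult-class].
#' @export
rdcvFit <- function(X, y, params = rdcvParams(),
                    task = c("regression", "classification")) {
  task <- match.arg(task)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  if (anyNA(X))
    stop("X contains missing values; impute upstream", call. = FALSE)
  if (task == "classification") {
    y <- factor(y)
    if (nlevels(y) < 2L)
      stop("classification requires at least two classes", call. = FALSE)
  } else {
    y <- as.numeric(y)
    if (stats::sd(y) == 0)
      stop("constant response: Q2 undefined", call. = FALSE)
  }
  n <- nrow(X)
  if (length(y) != n) stop("X and y disagree in length", call. = FALSE)

  perRep <- numeric(params@nRep)
  oof <- matrix(NA_real_, n, params@nRep)
  selMin <- selMid <- selMax <- integer(0)
  selVars <- character(0)
  for (r in seq_len(params@nRep)) {
    repSeed <- .streamSeed(params@seed + 17L * r, "rdcv")
    repOut <- withr::with_seed(repSeed, {
      fold <- .makeFolds(y, params@nOuter)
      preds <- if (is.factor(y)) factor(rep(NA, n), levels = levels(y))
               else numeric(n)
      opts <- list()
      for (o in seq_len(params@nOuter)) {
        tr <- fold != o
        vars <- colnames(X)
        if (params@varSel) {
          ladder <- .eliminationLadder(X[tr, , drop = FALSE], y[tr], params,
                                       seedBase = repSeed + 1000L * o)
          opt <- .ladderOptimum(ladder)
          vars <- opt$vars
          opts[[o]] <- opt
        }
        fit <- .fitRf(X[tr, vars, drop = FALSE], y[tr], params@nTrees,
                      seed = repSeed + o)
        preds[!tr] <- .predRf(fit, X[!tr, vars, drop = FALSE])
      }
      list(preds = preds, opts = opts)
    })
    predsR <- repOut$preds
    for (opt in repOut$opts) {
      selMin <- c(selMin, opt$nMin)
      selMid <- c(selMid, opt$nMid)
      selMax <- c(selMax, opt$nMax)
      selVars <- c(selVars, opt$vars)
    }
    if (task == "regression") {
      perRep[r] <- 1 - sum((y - predsR)^2) / sum((y - mean(y))^2)
      oof[, r] <- predsR
    } else {
      perRep[r] <- mean(predsR == y)
      oof[, r] <- as.integer(predsR)
    }
  }
  fit <- mean(perRep)
  selected <- if (params@varSel) {
    freq <- sort(table(selVars), decreasing = TRUE)
    list(nMin = as.integer(round(stats::median(selMin))),
         nMid = as.integer(round(stats::median(selMid))),
         nMax = as.integer(round(stats::median(selMax))),
         variables = names(freq)[seq_len(min(length(freq),
                                  max(1, round(stats::median(selMid)))))])
  } else list()
  methods::new("RdcvResult",
    task = task, fitness = fit, perRepetition = perRep, outOfFold = oof,
    selected = selected,
    thresholdPass = if (task == "regression") fit > 0.2 else fit > 0.6)
}

#' Median imputation of predictor matrices
#'
#' Per-feature median imputation of missing predictor values, applied
#' before any rdCV screen (tree learners tolerate this crude scheme).
#'
#' @param X numeric matrix.
#' @return X with `NA` cells replaced by their column medians.
#' @export
imputeMedian <- function(X) {
  X <- as.matrix(X)
  if (!anyNA(X)) return(X)
  med <- apply(X, 2, stats::median, na.rm = TRUE)
  idx <- which(is.na(X), arr.ind = TRUE)
  X[idx] <- med[idx[, 2]]
  X
}

#' Permutation test of an rdCV screen
#'
#' Re-runs the full repeated double cross-validation on `nPerm` uniform
#' permutations of the response and reports the plus-one estimator
#' `p = (1 + #\{permuted fitness >= observed\}) / (1 + nPerm)`, which is
#' bounded away from zero and unbiased as a p-value lower bound.
#'
#' @param X,y,params,task as in [rdcvFit()].
#' @param nPerm number of permutations (100 in the full protocol).
#' @param observed optionally, a precomputed [RdcvResult-class] for the
#'   unpermuted data.
#' @return list with `p`, `observed` (fitness), and `permuted` (fitness of
#'   each permutation).
#' @export
permutationTest <- function(X, y, params = rdcvParams(),
                            task = c("regression", "classification"),
                            nPerm = 100L, observed = NULL) {
  task <- match.arg(task)
  if (nPerm < 1L) stop("nPerm must be at least 1", call. = FALSE)
  if (is.null(observed)) observed <- rdcvFit(X, y, params, task)
  obs <- fitness(observed)
  permFit <- vapply(seq_len(nPerm), function(b) {
    yb <- withr::with_seed(.streamSeed(params@seed + b, "perm"), sample(y))
    pb <- params; pb@seed <- params@seed + 7919L * b
    fitness(rdcvFit(X, yb, pb, task))
  }, numeric(1))
  list(p = (1 + sum(permFit >= obs)) / (1 + nPerm),
       observed = obs, permuted = permFit)
}

#' Re-run protocol for passing classification models
#'
#' Downsampling discards subjects at random, so any classification model
#' whose first-pass CR exceeds 0.6 is re-fitted `nReruns` times, each with
#' a fresh seeded balanced downsample, and summarized as mean CR +/- SD
#' (SD reported as 0 for a single re-run). Optionally a permutation test is
#' run on the first re-run's downsample.
#'
#' @param X full predictor matrix (subjects in rows, named).
#' @param assignment the [ClusterAssignment-class] defining the classes;
#'   must pass [filterMinSize()].
#' @param params an [RdcvParams-class].
#' @param nReruns number of re-runs (default 5).
#' @param nPerm permutations for the accompanying test (0 = skip).
#' @return list with `meanCR`, `sdCR`, `perRun`, and `permP` (`NA` when
#'   `nPerm = 0`).
#' @export
rerunProtocol <- function(X, assignment, params = rdcvParams(),
                          nReruns = 5L, nPerm = 0L) {
  if (!filterMinSize(assignment))
    stop("assignment fails the minimum-cluster-size filter; ",
         "downsampling infeasible", call. = FALSE)
  lab <- clusterLabels(assignment)
  crs <- numeric(nReruns)
  permP <- NA_real_
  for (i in seq_len(nReruns)) {
    keep <- downsampleBalanced(assignment, seed = params@seed + 131L * i)
    pb <- params; pb@seed <- params@seed + i
    res <- rdcvFit(X[keep, , drop = FALSE], factor(lab[keep]), pb,
                   "classification")
    crs[i] <- fitness(res)
    if (i == 1L && nPerm > 0L)
      permP <- permutationTest(X[keep, , drop = FALSE], factor(lab[keep]),
                               pb, "classification", nPerm = nPerm,
                               observed = res)$p
  }
  list(meanCR = mean(crs),
       sdCR = if (nReruns > 1L) stats::sd(crs) else 0,
       perRun = crs, permP = permP)
}
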