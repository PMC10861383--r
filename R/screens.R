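#' @include rdcv.R
NULL

.REGRESSION_PREDICTORS <- c("microbiota", "scfa", "metabolome", "clinical",
                            "combination")
## combination in the classification screen excludes the clinical block
.CLASSIFICATION_PREDICTORS <- c("microbiota", "scfa", "metabolome",
                                "combination")

## clinical table as a numeric matrix (factors -> integer codes; RF splits
## on codes are order-agnostic enough for screening purposes)
.clinicalMatrix <- function(dataset) {
  df <- clinicalData(dataset)
  m <- vapply(df, function(col) {
    if (is.numeric(col)) col else as.numeric(as.factor(col))
  }, numeric(nrow(df)))
  rownames(m) <- rownames(df)
  m
}

#' Assemble a predictor matrix for one screen
#'
#' Maps a predictor-set name onto a subjects x features numeric matrix:
#' the single blocks as generated, `scfa` as the fecal and plasma matrices
#' side by side, and `combination` as the concatenation of all blocks with
#' per-block column standardization (tree learners are scale-invariant, but
#' standardization keeps the combined block interpretable). The clinical
#' block is part of the combination only when `includeClinical = TRUE`
#' (the regression screen); the classification screen combines the three
#' molecular blocks.
#'
#' @param dataset a [TrialDataset-class].
#' @param set one of `microbiota`, `scfa`, `metabolome`, `clinical`,
#'   `combination`.
#' @param includeClinical include the clinical block in `combination`?
#' @return numeric matrix, subjects in rows.
#' @export
predictorMatrix <- function(dataset, set, includeClinical = TRUE) {
  pre <- function(m, tag) {
    colnames(m) <- paste(tag, colnames(m), sep = ".")
    m
  }
  out <- switch(set,
    microbiota = baselineBlock(dataset, "microbiota"),
    metabolome = baselineBlock(dataset, "metabolome"),
    scfa = cbind(pre(baselineBlock(dataset, "fecal_scfa"), "fecal"),
                 pre(baselineBlock(dataset, "plasma_scfa"), "plasma")),
    clinical = .clinicalMatrix(dataset),
    combination = {
      parts <- list(
        microbiota = baselineBlock(dataset, "microbiota"),
        scfa = cbind(pre(baselineBlock(dataset, "fecal_scfa"), "fecal"),
                     pre(baselineBlock(dataset, "plasma_scfa"), "plasma")),
        metabolome = baselineBlock(dataset, "metabolome"))
      if (includeClinical) parts$clinical <- .clinicalMatrix(dataset)
      std <- lapply(names(parts), function(nm) {
        m <- scale(parts[[nm]])
        m[, attr(m, "scaled:scale") > 0, drop = FALSE]
      })
      do.call(cbind, std)
    },
    stop("unknown predictor set: ", set, call. = FALSE))
  imputeMedian(out)
}

#' Enumerate the baseline screen configurations
#'
#' The regression screen crosses 6 IBS-SSS variables x 3 representations x
#' 3 arms x 5 predictor sets = 270 model configurations; the classification
#' screen crosses 6 variables x 3 representations x 2 clustering methods x
#' 2 scalings x 3 k-values x 4 predictor sets = 864. Order is
#' deterministic (lexicographic over the grid).
#'
#' @param task `regression` or `classification`.
#' @return data.frame with one row per model configuration.
#' @examples
#' nrow(enumerateBaselineScreens("regression"))      # 270
#' nrow(enumerateBaselineScreens("classification"))  # 864
#' @export
enumerateBaselineScreens <- function(task = c("regression",
                                              "classification")) {
  task <- match.arg(task)
  if (task == "regression") {
    g <- expand.grid(predictor = .REGRESSION_PREDICTORS,
                     arm = trialArms(),
                     representation = responseRepresentations(),
                     item = responseItems(),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    g <- g[, c("item", "representation", "arm", "predictor")]
  } else {
    g <- expand.grid(predictor = .CLASSIFICATION_PREDICTORS,
                     k = 2:4, scaled = c(FALSE, TRUE),
                     method = c("hierarchical", "kmeans"),
                     representation = responseRepresentations(),
                     item = responseItems(),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    g <- g[, c("item", "representation", "method", "scaled", "k",
               "predictor")]
  }
  rownames(g) <- NULL
  g
}

#' Run the baseline regression screen
#'
#' For each configuration (or a subset), condenses the response frame,
#' extracts the response of the configured arm, and fits the rdCV
#' random-forest regression. Models passing the a priori filter Q2 > 0.2
#' are permutation-tested.
#'
#' @param dataset a [TrialDataset-class].
#' @param params an [RdcvParams-class].
#' @param configs rows of [enumerateBaselineScreens()]`("regression")`
#'   (default: all 270).
#' @param nPerm permutations for passing models (0 = skip).
#' @return data.frame: one row per configuration with `Q2`,
#'   `threshold_pass` and `p_perm` columns.
#' @export
screenRegression <- function(dataset, params = rdcvParams(),
                             configs = NULL, nPerm = 0L) {
  if (is.null(configs)) configs <- enumerateBaselineScreens("regression")
  preds <- new.env(parent = emptyenv())
  getX <- function(set) {
    if (is.null(preds[[set]]))
      assign(set, predictorMatrix(dataset, set, includeClinical = TRUE),
             envir = preds)
    preds[[set]]
  }
  out <- configs
  out$Q2 <- NA_real_
  out$threshold_pass <- FALSE
  out$p_perm <- NA_real_
  for (i in seq_len(nrow(configs))) {
    cf <- configs[i, ]
    frame <- condenseResponseFrame(dataset, cf$item, cf$representation)
    y <- responseValues(frame)[, cf$arm]
    X <- getX(cf$predictor)[names(y), , drop = FALSE]
    res <- rdcvFit(X, y, params, "regression")
    out$Q2[i] <- fitness(res)
    out$threshold_pass[i] <- thresholdPass(res)
    if (thresholdPass(res) && nPerm > 0L)
      out$p_perm[i] <- permutationTest(X, y, params, "regression",
                                       nPerm = nPerm, observed = res)$p
  }
  out
}

#' Run the baseline classification screen
#'
#' For each configuration: cluster the condensed response frame, apply the
#' minimum-size filter (>= `minN` per cluster), randomly downsample to
#' balanced classes, and fit the rdCV random-forest classifier. Models with
#' CR above the a priori 0.6 filter enter the re-run protocol (`nReruns`
#' fresh downsamples, mean CR +/- SD) with a permutation test.
#'
#' @param dataset a [TrialDataset-class].
#' @param params an [RdcvParams-class].
#' @param configs rows of [enumerateBaselineScreens()]`("classification")`
#'   (default: all 864).
#' @param minN minimum cluster size (default 8).
#' @param nReruns re-runs for passing models (default 5).
#' @param nPerm permutations for passing models (0 = skip).
#' @return data.frame: one row per configuration with `eligible`, `CR`,
#'   `threshold_pass`, `rerun_mean_cr`, `rerun_sd_cr`, `p_perm`.
#' @export
screenClassification <- function(dataset, params = rdcvParams(),
                                 configs = NULL, minN = 8L,
                                 nReruns = 5L, nPerm = 0L) {
  if (is.null(configs))
    configs <- enumerateBaselineScreens("classification")
  preds <- new.env(parent = emptyenv())
  getX <- function(set) {
    if (is.null(preds[[set]]))
      assign(set, predictorMatrix(dataset, set, includeClinical = FALSE),
             envir = preds)
    preds[[set]]
  }
  out <- configs
  out$eligible <- FALSE
  out$CR <- NA_real_
  out$threshold_pass <- FALSE
  out$rerun_mean_cr <- NA_real_
  out$rerun_sd_cr <- NA_real_
  out$p_perm <- NA_real_
  for (i in seq_len(nrow(configs))) {
    cf <- configs[i, ]
    frame <- condenseResponseFrame(dataset, cf$item, cf$representation)
    asg <- clusterResponses(frame, cf$method, cf$k, cf$scaled,
                            seed = params@seed)
    if (!filterMinSize(asg, minN)) next
    out$eligible[i] <- TRUE
    X <- getX(cf$predictor)
    lab <- clusterLabels(asg)
    keep <- downsampleBalanced(asg, seed = params@seed)
    res <- rdcvFit(X[keep, , drop = FALSE], factor(lab[keep]), params,
                   "classification")
    out$CR[i] <- fitness(res)
    out$threshold_pass[i] <- thresholdPass(res)
    if (thresholdPass(res)) {
      rr <- rerunProtocol(X, asg, params, nReruns = nReruns, nPerm = nPerm)
      out$rerun_mean_cr[i] <- rr$meanCR
      out$rerun_sd_cr[i] <- rr$sdCR
      out$p_perm[i] <- rr$permP
    }
  }
  out
}
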