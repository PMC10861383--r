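#' @include screens.R
NULL

#' Predictor representations of the provocation-test tensor
#'
#' Flattens the (complete) provocation tensor into a subjects x features
#' predictor matrix under one of the four representations screened:
#' \describe{
#'   \item{`timepoint`}{the slice at one of the 8 draw minutes
#'     (`minute` required; -10 is the pre-test draw).}
#'   \item{`auc`}{the trapezoidal area under each subject-feature curve
#'     over minutes -10 to 240.}
#'   \item{`logratio`}{`log2(x_t / x_pre)` for one post-pre timepoint
#'     (`minute` required; intensities must be positive).}
#'   \item{`combined`}{the pre-test slice column-bound with one later
#'     slice (`minute` required).}
#' }
#'
#' @param tensor a complete [ProvocationTensor-class] (run
#'   [imputeTensor()] first if cells are missing).
#' @param mode one of the four representations.
#' @param minute which timepoint, for the modes that need one.
#' @return numeric matrix, subjects in rows.
#' @export
provocationRepresentation <- function(tensor,
                                      mode = c("timepoint", "auc",
                                               "logratio", "combined"),
                                      minute = NULL) {
  mode <- match.arg(mode)
  vals <- tensorValues(tensor)
  if (anyNA(vals))
    stop("tensor has missing cells; impute first", call. = FALSE)
  mins <- timeMinutes(tensor)
  slice <- function(m) {
    i <- match(m, mins)
    if (is.na(i)) stop("no timepoint at minute ", m, call. = FALSE)
    s <- vals[, , i]
    dimnames(s) <- list(tensor@subjectIds, tensor@featureIds)
    s
  }
  pick <- function() {
    if (is.null(minute))
      stop("mode '", mode, "' needs a minute", call. = FALSE)
    minute
  }
  switch(mode,
    timepoint = slice(pick()),
    auc = {
      ## trapezoid over the draw schedule, per subject-feature curve
      w <- diff(mins)
      out <- matrix(0, nrow(vals), ncol(vals),
                    dimnames = list(tensor@subjectIds, tensor@featureIds))
      for (i in seq_along(w))
        out <- out + w[i] * (vals[, , i] + vals[, , i + 1]) / 2
      out
    },
    logratio = {
      m <- pick()
      if (m == mins[1])
        stop("logratio needs a post-pre timepoint", call. = FALSE)
      a <- slice(m); pre <- slice(mins[1])
      if (any(a <= 0) || any(pre <= 0))
        stop("logratio requires positive intensities", call. = FALSE)
      out <- log2(a / pre)
      colnames(out) <- paste0(colnames(out), ".lr", m)
      out
    },
    combined = {
      m <- pick()
      pre <- slice(mins[1]); later <- slice(m)
      colnames(pre) <- paste0(colnames(pre), ".pre")
      colnames(later) <- paste0(colnames(later), ".t", m)
      cbind(pre, later)
    })
}

#' Enumerate the provocation screen configurations
#'
#' The representations are: each of the 8 timepoints, the AUC, 7 log-ratios
#' against the pre-test draw, and 7 pre-test + later-timepoint pairs — 23
#' in all — crossed with the 3 arms (total IBS-SSS score, absolute values)
#' for 69 regression configurations.
#'
#' @param minutes the draw schedule (default [provocationMinutes()]).
#' @return data.frame with columns `arm`, `mode`, `minute` (NA for `auc`).
#' @examples
#' nrow(enumerateProvocationScreens())  # 69
#' @export
enumerateProvocationScreens <- function(minutes = provocationMinutes()) {
  reps <- rbind(
    data.frame(mode = "timepoint", minute = minutes),
    data.frame(mode = "auc", minute = NA_real_),
    data.frame(mode = "logratio", minute = minutes[-1]),
    data.frame(mode = "combined", minute = minutes[-1]))
  g <- merge(data.frame(arm = trialArms()), reps, by = NULL)
  g <- g[order(g$arm, g$mode, g$minute, na.last = TRUE), ]
  rownames(g) <- NULL
  g
}

#' Run the provocation regression screen
#'
#' Models the total IBS-SSS score of each arm (absolute values) from every
#' provocation-tensor representation with rdCV random-forest regression;
#' models passing Q2 > 0.2 are permutation-tested.
#'
#' @param dataset a [TrialDataset-class].
#' @param tensor a complete [ProvocationTensor-class].
#' @param params an [RdcvParams-class].
#' @param configs rows of [enumerateProvocationScreens()] (default: all 69).
#' @param nPerm permutations for passing models (0 = skip).
#' @return data.frame with `Q2`, `threshold_pass`, `p_perm` per
#'   configuration.
#' @export
screenProvocation <- function(dataset, tensor, params = rdcvParams(),
                              configs = NULL, nPerm = 0L) {
  if (is.null(configs)) configs <- enumerateProvocationScreens()
  frame <- condenseResponseFrame(dataset, "total", "absolute")
  out <- configs
  out$Q2 <- NA_real_
  out$threshold_pass <- FALSE
  out$p_perm <- NA_real_
  for (i in seq_len(nrow(configs))) {
    cf <- configs[i, ]
    X <- provocationRepresentation(tensor, cf$mode,
                                   if (is.na(cf$minute)) NULL else cf$minute)
    y <- responseValues(frame)[, cf$arm]
    X <- X[names(y), , drop = FALSE]
    res <- rdcvFit(X, y, params, "regression")
    out$Q2[i] <- fitness(res)
    out$threshold_pass[i] <- thresholdPass(res)
    if (thresholdPass(res) && nPerm > 0L)
      out$p_perm[i] <- permutationTest(X, y, params, "regression",
                                       nPerm = nPerm, observed = res)$p
  }
  out
}
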