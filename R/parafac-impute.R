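#' @include provocation.R
NULL

#' Low-rank matrix-completion imputation of a provocation tensor
#'
#' Imputes masked cells by iterative truncated-SVD completion on the
#' subject x (feature, timepoint) unfolding: missing cells are initialized
#' with their subject-feature fiber mean, then the unfolding is repeatedly
#' reconstructed at the given rank with observed cells restored after each
#' pass, until the relative change of the matrix falls below `tol`.
#' Observed cells are returned unchanged.
#'
#' @param tensor a [ProvocationTensor-class]; every subject-feature fiber
#'   must have at least one observed timepoint.
#' @param rank truncation rank of the completion (default 5).
#' @param tol relative-change stopping tolerance (default 1e-6).
#' @param maxIter iteration cap; exceeding it is an error with diagnostics.
#' @return A complete [ProvocationTensor-class] (empty mask).
#' @export
imputeTensor <- function(tensor, rank = 5L, tol = 1e-6, maxIter = 200L) {
  mask <- missingMask(tensor)
  if (!any(mask)) return(tensor)
  vals <- tensorValues(tensor)
  d <- dim(vals)
  fiberMean <- apply(vals, c(1, 2), mean, na.rm = TRUE)
  if (anyNA(fiberMean))
    stop("a subject-feature fiber is fully missing; cannot impute",
         call. = FALSE)
  M <- matrix(vals, d[1], d[2] * d[3])
  Mmask <- matrix(mask, d[1], d[2] * d[3])
  init <- matrix(rep(fiberMean, d[3]), d[1], d[2] * d[3])
  M[Mmask] <- init[Mmask]
  rank <- min(rank, d[1] - 1L, ncol(M) - 1L)
  for (it in seq_len(maxIter)) {
    sv <- svd(M, nu = rank, nv = rank)
    rec <- sv$u %*% (sv$d[seq_len(rank)] * t(sv$v))
    Mnew <- M
    Mnew[Mmask] <- rec[Mmask]
    delta <- sqrt(sum((Mnew - M)^2)) / sqrt(sum(M^2))
    M <- Mnew
    if (delta < tol) {
      out <- tensor
      out@values <- array(M, dim = d)
      out@mask <- array(FALSE, dim = d)
      return(out)
    }
  }
  stop(sprintf(
    "matrix completion did not converge in %d iterations (last relative change %.3g, rank %d)",
    maxIter, delta, rank), call. = FALSE)
}

#' Preprocess a provocation tensor for PARAFAC
#'
#' The two preprocessing schemes applied before decomposition:
#' \describe{
#'   \item{`sd_one`}{each metabolite feature's unfolded vector (over
#'     subjects and timepoints) is divided by its standard deviation.}
#'   \item{`centered_rms_one`}{each subject's global metabolite average
#'     (mean over all features and timepoints, or per timepoint with
#'     `centerScope = "subject_timepoint"`) is subtracted, then each
#'     feature's unfolded vector is divided by its root mean square.}
#' }
#' Zero-variance (or zero-RMS) features are dropped with a warning.
#'
#' @param tensor a complete [ProvocationTensor-class].
#' @param scheme `sd_one` or `centered_rms_one`.
#' @param centerScope centering scope for scheme `centered_rms_one`:
#'   one global mean per subject (default) or one per subject-timepoint.
#' @return A preprocessed [ProvocationTensor-class].
#' @export
preprocessTensor <- function(tensor,
                             scheme = c("sd_one", "centered_rms_one"),
                             centerScope = c("subject",
                                             "subject_timepoint")) {
  scheme <- match.arg(scheme)
  centerScope <- match.arg(centerScope)
  vals <- tensorValues(tensor)
  if (anyNA(vals))
    stop("tensor has missing cells; impute first", call. = FALSE)
  d <- dim(vals)
  if (scheme == "centered_rms_one") {
    if (centerScope == "subject") {
      vals <- vals - array(apply(vals, 1, mean), dim = d)
    } else {
      m <- apply(vals, c(1, 3), mean)                    # subject x time
      vals <- vals - aperm(array(m, dim = c(d[1], d[3], d[2])), c(1, 3, 2))
    }
  }
  ## per-feature scale over the subject x timepoint unfolding
  featMat <- matrix(aperm(vals, c(1, 3, 2)), d[1] * d[3], d[2])
  sc <- if (scheme == "sd_one") apply(featMat, 2, stats::sd)
        else sqrt(colMeans(featMat^2))
  keep <- sc > 0
  if (!all(keep))
    warning(sum(!keep), " zero-variance feature(s) dropped", call. = FALSE)
  vals <- vals[, keep, , drop = FALSE]
  vals <- sweep(vals, 2, sc[keep], "/")
  out <- tensor
  out@values <- vals
  out@mask <- array(FALSE, dim = dim(vals))
  out@featureIds <- tensor@featureIds[keep]
  methods::validObject(out)
  out
}
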