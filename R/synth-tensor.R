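#' @include synth-trial.R
NULL

#' Simulate a postprandial provocation-test tensor
#'
#' Builds a subjects x features x timepoints [ProvocationTensor-class] as a
#' sum of `tensorRank` rank-1 trilinear components plus noise:
#' `X = sum_r a_r (o) b_r (o) d_r + E`. Factor entries are log-normal by
#' default so intensities stay positive; with `orthogonal = TRUE` the factor
#' matrices are orthonormalized (QR) and components scaled with distinct
#' magnitudes, the construction used for decomposition-recovery checks.
#' Component-1 subject scores can be shifted between the hidden classes of
#' `dataset` (`tensorClassEffect`, standardized units). Generator factors
#' are stored in the object's ground truth for recovery tests. A mask of
#' exactly `floor(missingRate * n*p*t)` cells is drawn uniformly at random;
#' a mask leaving any subject x feature fiber fully missing is rejected
#' with an error.
#'
#' @param config a [SimConfig-class].
#' @param dataset the [TrialDataset-class] whose subjects (and hidden
#'   classes) the tensor covers.
#' @param orthogonal orthonormalize factors per mode (recovery-test
#'   construction; intensities may then be negative).
#' @return A [ProvocationTensor-class]; masked cells hold `NA`.
#' @examples
#' cfg <- simConfig(nSubjects = 12, nMetabolomeFeatures = 20, seed = 3)
#' tens <- simulateProvocationTensor(cfg, simulateTrial(cfg))
#' tens
#' @export
simulateProvocationTensor <- function(config, dataset,
                                      orthogonal = FALSE) {
  methods::validObject(config)
  stopifnot(config@tensorRank >= 1L)
  n <- length(subjectIds(dataset))
  p <- config@nMetabolomeFeatures
  tt <- length(config@timepoints)
  R <- config@tensorRank

  made <- .withStream(config@seed, "tensor", {
    if (orthogonal) {
      A <- qr.Q(qr(matrix(stats::rnorm(n * R), n)))
      B <- qr.Q(qr(matrix(stats::rnorm(p * R), p)))
      D <- qr.Q(qr(matrix(stats::rnorm(tt * R), tt)))
      A <- A %*% diag(seq(R, 1), R)      # distinct magnitudes -> identifiable
    } else {
      A <- matrix(exp(stats::rnorm(n * R, 0, 0.4)), n)
      B <- matrix(exp(stats::rnorm(p * R, 0, 0.4)), p)
      D <- matrix(exp(stats::rnorm(tt * R, 0, 0.4)), tt)
    }
    if (config@tensorClassEffect != 0 && length(trueClass(dataset))) {
      cls <- trueClass(dataset)
      if (length(unique(cls)) > 1L) {
        ind <- as.numeric(scale(as.numeric(cls)))
        A[, 1] <- A[, 1] + config@tensorClassEffect * stats::sd(A[, 1]) * ind
      }
    }
    low <- array(0, dim = c(n, p, tt))
    for (r in seq_len(R))
      low <- low + outer(outer(A[, r], B[, r]), D[, r])
    vals <- low
    if (config@noiseSd$tensor > 0) {
      rms <- sqrt(mean(low^2))
      vals <- low + array(stats::rnorm(n * p * tt, 0,
                                       config@noiseSd$tensor * rms),
                          dim = dim(low))
      if (!orthogonal) vals <- pmax(vals, 1e-6)  # keep intensities positive
    }
    list(values = vals, A = A, B = B, D = D)
  })

  mask <- .withStream(config@seed, "mask", {
    m <- array(FALSE, dim = c(n, p, tt))
    nMask <- floor(config@missingRate * n * p * tt)
    if (nMask > 0) {
      m[sample.int(n * p * tt, nMask)] <- TRUE
      fiberAllMissing <- apply(m, c(1, 2), all)
      if (any(fiberAllMissing))
        stop("missingRate leaves a subject-feature fiber fully missing; ",
             "lower the rate or change the seed", call. = FALSE)
    }
    m
  })

  vals <- made$values
  vals[mask] <- NA_real_
  methods::new("ProvocationTensor",
    values     = vals,
    mask       = mask,
    minutes    = config@timepoints,
    subjectIds = subjectIds(dataset),
    featureIds = sprintf("met_%04d", seq_len(p)),
    groundTruth = list(A = made$A, B = made$B, D = made$D)
  )
}
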