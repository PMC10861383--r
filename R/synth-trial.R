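#' @include sim-config.R
NULL

.SCFA_NAMES <- c("formate", "acetate", "propionate", "butyrate",
                 "isobutyrate", "valerate", "isovalerate", "caproate",
                 "succinate")

## Truncated-normal draws by inverse CDF (exact, no rejection loop).
.rtnorm <- function(n, mean, sd, lower, upper) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

.rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

## Resolve which blocks a molecularShift entry targets ("scfa" hits both
## matrices) and validate the feature indices.
.shiftTargets <- function(ms, blockCols) {
  blocks <- if (ms$block == "scfa") c("fecal_scfa", "plasma_scfa") else ms$block
  for (b in blocks) {
    if (!b %in% names(blockCols))
      stop("molecularShift targets unknown block: ", b, call. = FALSE)
    if (any(ms$features < 1L | ms$features > blockCols[[b]]))
      stop("molecularShift targets a feature index out of range in block '",
           b, "'", call. = FALSE)
  }
  blocks
}

#' Simulate a three-arm crossover provocation trial
#'
#' Generates a [TrialDataset-class] with the statistical structure the
#' downstream screens assume. Symptom scores arise from a per-subject latent
#' severity (normal, mean 250, sd 60, truncated to the 0--500 total scale)
#' apportioned to the five IBS-SSS items by a subject-specific
#' Dirichlet(2,2,2,2,2) split; each arm x week record adds occasion noise,
#' and planted metabotypes add their configured response shift to the
#' intervention week before items are clipped to \[0, 100\]. Molecular
#' blocks are log-normal (logistic-normal with closure for the microbiota);
#' planted molecular shifts act as standardized location shifts on the log
#' scale, with compositional blocks renormalized afterwards. Every block
#' draws from its own RNG stream derived from the master seed, so resizing
#' one block never changes another.
#'
#' @param config a [SimConfig-class] from [simConfig()].
#' @return A [TrialDataset-class]; `trueClass(x)` holds the hidden labels.
#' @examples
#' ds <- simulateTrial(simConfig(nSubjects = 16, nMetabolomeFeatures = 30,
#'                               seed = 7))
#' ds
#' @export
simulateTrial <- function(config) {
  methods::validObject(config)
  n <- config@nSubjects
  seed <- config@seed
  ids <- sprintf("S%03d", seq_len(n))

  cls <- .withStream(seed, "classes",
    sample.int(config@nClasses, n, replace = TRUE,
               prob = config@classProportions))

  sss <- .withStream(seed, "sss", {
    latent <- .rtnorm(n, 250, 60, 0, 500)
    w <- .rdirichlet(n, rep(2, 5))
    arr <- array(0, dim = c(n, 3L, 2L, 5L),
                 dimnames = list(ids, trialArms(), .WEEK_TYPES, sssItems()))
    for (a in seq_len(3L)) {
      for (wk in seq_len(2L)) {
        occ <- stats::rnorm(n, 0, config@noiseSd$sss)
        base <- w * (latent + occ)          # items share the record noise
        if (wk == 1L)                        # intervention week gets the shift
          base <- base + matrix(config@responseShift[cls, a, ], ncol = 5L)
        arr[, a, wk, ] <- pmin(pmax(base, 0), 100)
      }
    }
    arr
  })

  blockCols <- c(microbiota = config@nGenera,
                 fecal_scfa = config@nScfa,
                 plasma_scfa = config@nScfa,
                 metabolome = config@nMetabolomeFeatures,
                 clinical = config@nClinicalContinuous)
  ## planted log-scale shifts per block column, per class
  logShift <- lapply(names(blockCols), function(b)
    matrix(0, config@nClasses, blockCols[[b]]))
  names(logShift) <- names(blockCols)
  for (ms in config@molecularShift) {
    for (b in .shiftTargets(ms, blockCols)) {
      sdLog <- switch(b,
        microbiota = config@noiseSd$microbiota,
        fecal_scfa = , plasma_scfa = config@noiseSd$scfa,
        metabolome = config@noiseSd$metabolome,
        clinical = 1)
      logShift[[b]][, ms$features] <- logShift[[b]][, ms$features] +
        ms$d * sdLog
    }
  }

  microbiota <- .withStream(seed, "microbiota", {
    mu <- stats::rnorm(config@nGenera, 0, 1.5)   # genus-level abundance spread
    z <- matrix(stats::rnorm(n * config@nGenera, 0, config@noiseSd$microbiota),
                n) + rep(mu, each = n)
    z <- z + logShift$microbiota[cls, , drop = FALSE]
    rel <- exp(z)
    rel <- rel / rowSums(rel)                    # compositional closure
    dimnames(rel) <- list(ids, sprintf("genus_%03d", seq_len(config@nGenera)))
    rel
  })

  scfa <- .withStream(seed, "scfa", {
    nms <- if (config@nScfa == 9L) .SCFA_NAMES
           else sprintf("scfa_%02d", seq_len(config@nScfa))
    mk <- function(which) {
      mu <- stats::rnorm(config@nScfa, log(50), 1)
      z <- matrix(stats::rnorm(n * config@nScfa, 0, config@noiseSd$scfa),
                  n) + rep(mu, each = n)
      z <- z + logShift[[which]][cls, , drop = FALSE]
      m <- exp(z)
      dimnames(m) <- list(ids, nms)
      m
    }
    list(fecal = mk("fecal_scfa"), plasma = mk("plasma_scfa"))
  })

  metabolome <- .withStream(seed, "metabolome", {
    p <- config@nMetabolomeFeatures
    mu <- stats::runif(p, log(1e3), log(1e6))
    z <- matrix(stats::rnorm(n * p, 0, config@noiseSd$metabolome), n) +
      rep(mu, each = n)
    z <- z + logShift$metabolome[cls, , drop = FALSE]
    m <- exp(z)
    dimnames(m) <- list(ids, sprintf("met_%04d", seq_len(p)))
    m
  })

  clinical <- .withStream(seed, "clinical", {
    nc <- config@nClinicalContinuous
    nk <- config@nClinicalCategorical
    cont <- matrix(stats::rnorm(n * nc), n) +
      rep(stats::runif(nc, -1, 1), each = n)
    cont <- cont + logShift$clinical[cls, , drop = FALSE]
    colnames(cont) <- sprintf("clin_cont_%02d", seq_len(nc))
    df <- as.data.frame(cont)
    for (j in seq_len(nk)) {
      nLev <- sample(2:4, 1)
      df[[sprintf("clin_cat_%02d", j)]] <-
        factor(sample(LETTERS[seq_len(nLev)], n, replace = TRUE))
    }
    rownames(df) <- ids
    df
  })

  methods::new("TrialDataset",
    subjectIds = ids,
    sss        = sss,
    blocks     = list(microbiota = microbiota,
                      fecal_scfa = scfa$fecal,
                      plasma_scfa = scfa$plasma,
                      metabolome = metabolome),
    clinical   = clinical,
    trueClass  = as.integer(cls),
    groundTruth = list(responseShift = config@responseShift,
                       molecularShift = config@molecularShift,
                       seed = seed)
  )
}
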