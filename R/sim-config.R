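#' @include AllClasses.R
NULL

#' SimConfig: parameters of the synthetic crossover-trial generator
#'
#' Holds everything the generator needs: cohort and block sizes, the
#' provocation-test schedule, the metabotype structure (class proportions,
#' symptom shifts per class/arm/item, molecular shifts per block), the
#' planted tensor rank, and noise scales. `nClasses = 1` with zero shifts is
#' the global-null mode.
#'
#' @slot nSubjects number of analyzable subjects (default 74).
#' @slot nMetabolomeFeatures untargeted plasma metabolome features
#'   (default 500; a full study produces thousands).
#' @slot nGenera genus-level microbiota features (default 132).
#' @slot nScfa SCFAs per matrix, duplicated for feces and plasma (default 9).
#' @slot nClinicalContinuous,nClinicalCategorical clinical/questionnaire
#'   variables (defaults 24 and 6).
#' @slot timepoints provocation blood-draw minutes, strictly increasing.
#' @slot nClasses number of planted metabotypes; 1 = global null.
#' @slot classProportions simplex weights over classes (sum to 1).
#' @slot responseShift numeric array `nClasses x 3 arms x 5 items` of
#'   additive IBS-SSS effects (points) applied to the intervention week.
#' @slot molecularShift list of planted block effects, each a list with
#'   `block`, `features` (column indices) and `d` (standardized mean
#'   difference per class, on the log scale).
#' @slot tensorRank number of planted trilinear components.
#' @slot tensorClassEffect standardized shift of component-1 subject scores
#'   between classes (0 = none).
#' @slot noiseSd named list of residual scales: `sss` (points, occasion
#'   level), `microbiota`, `scfa`, `metabolome` (log scale), `tensor`
#'   (relative to the planted signal RMS).
#' @slot missingRate fraction of tensor cells masked, in \[0, 1).
#' @slot seed master RNG seed; every block draws from its own derived
#'   stream.
#'
#' @seealso [simConfig()], [simulateTrial()], [simulateProvocationTensor()]
#' @export
setClass("SimConfig",
  representation(
    nSubjects            = "integer",
    nMetabolomeFeatures  = "integer",
    nGenera              = "integer",
    nScfa                = "integer",
    nClinicalContinuous  = "integer",
    nClinicalCategorical = "integer",
    timepoints           = "numeric",
    nClasses             = "integer",
    classProportions     = "numeric",
    responseShift        = "array",
    molecularShift       = "list",
    tensorRank           = "integer",
    tensorClassEffect    = "numeric",
    noiseSd              = "list",
    missingRate          = "numeric",
    seed                 = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  counts <- c(object@nSubjects, object@nMetabolomeFeatures, object@nGenera,
              object@nScfa, object@nClasses, object@tensorRank)
  if (any(counts < 1L))
    msg <- c(msg, "all counts must be positive")
  if (length(object@classProportions) != object@nClasses)
    msg <- c(msg, "one class proportion per class required")
  if (abs(sum(object@classProportions) - 1) > 1e-8)
    msg <- c(msg, "class proportions must sum to 1")
  if (any(object@classProportions <= 0))
    msg <- c(msg, "class proportions must be positive")
  if (is.unsorted(object@timepoints, strictly = TRUE))
    msg <- c(msg, "timepoints must be strictly increasing")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must lie in [0, 1)")
  d <- dim(object@responseShift)
  if (!identical(d, c(object@nClasses, 3L, 5L)))
    msg <- c(msg, "responseShift must be an nClasses x 3 x 5 array")
  need <- c("sss", "microbiota", "scfa", "metabolome", "tensor")
  if (!all(need %in% names(object@noiseSd)))
    msg <- c(msg, "noiseSd must name sss, microbiota, scfa, metabolome, tensor")
  for (ms in object@molecularShift) {
    if (!all(c("block", "features", "d") %in% names(ms)))
      msg <- c(msg, "each molecularShift entry needs block, features, d")
    else if (length(ms$d) != object@nClasses)
      msg <- c(msg, "molecularShift d must give one effect per class")
  }
  if (length(msg)) msg else TRUE
})

#' Build a generator configuration
#'
#' Constructor for [SimConfig-class]. Defaults mirror the analyzed cohort of
#' the trial the package models: 74 subjects, 132 genera, 9 SCFAs in each of
#' two matrices, a high-dimensional metabolome block (500 features at desk
#' scale), and 8 provocation timepoints.
#'
#' @param nSubjects,nMetabolomeFeatures,nGenera,nScfa,nClinicalContinuous,nClinicalCategorical
#'   block sizes; see [SimConfig-class].
#' @param timepoints provocation minutes (default [provocationMinutes()]).
#' @param nClasses planted metabotype count (1 = global null).
#' @param classProportions simplex weights; default equal.
#' @param responseShift `NULL` (no effect), an `nClasses x 3` matrix of
#'   total-score shifts (split equally over the five items), or a full
#'   `nClasses x 3 x 5` per-item array. Points on the IBS-SSS scale.
#' @param molecularShift list of planted block effects (see
#'   [SimConfig-class]); default none.
#' @param tensorRank planted trilinear components (default 3).
#' @param tensorClassEffect class shift on component-1 subject scores.
#' @param noiseSd named list overriding any of the default residual scales
#'   `list(sss = 30, microbiota = 1, scfa = 0.5, metabolome = 1,
#'   tensor = 0.1)`.
#' @param missingRate fraction of tensor cells masked (default 0.05).
#' @param seed master seed (integer).
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nSubjects = 20, nMetabolomeFeatures = 50, seed = 1)
#' @export
simConfig <- function(nSubjects = 74L,
                      nMetabolomeFeatures = 500L,
                      nGenera = 132L,
                      nScfa = 9L,
                      nClinicalContinuous = 24L,
                      nClinicalCategorical = 6L,
                      timepoints = provocationMinutes(),
                      nClasses = 1L,
                      classProportions = NULL,
                      responseShift = NULL,
                      molecularShift = list(),
                      tensorRank = 3L,
                      tensorClassEffect = 0,
                      noiseSd = list(),
                      missingRate = 0.05,
                      seed = 1L) {
  nClasses <- as.integer(nClasses)
  if (is.null(classProportions))
    classProportions <- rep(1 / nClasses, nClasses)
  shift <- array(0, dim = c(nClasses, 3L, 5L),
                 dimnames = list(NULL, trialArms(), sssItems()))
  if (!is.null(responseShift)) {
    if (is.matrix(responseShift)) {
      for (it in seq_len(5L)) shift[, , it] <- responseShift / 5
    } else if (length(dim(responseShift)) == 3L) {
      shift[] <- responseShift
    } else stop("responseShift must be a matrix or 3-d array", call. = FALSE)
  }
  defaults <- list(sss = 30, microbiota = 1, scfa = 0.5,
                   metabolome = 1, tensor = 0.1)
  defaults[names(noiseSd)] <- noiseSd
  methods::new("SimConfig",
    nSubjects            = as.integer(nSubjects),
    nMetabolomeFeatures  = as.integer(nMetabolomeFeatures),
    nGenera              = as.integer(nGenera),
    nScfa                = as.integer(nScfa),
    nClinicalContinuous  = as.integer(nClinicalContinuous),
    nClinicalCategorical = as.integer(nClinicalCategorical),
    timepoints           = as.numeric(timepoints),
    nClasses             = nClasses,
    classProportions     = as.numeric(classProportions),
    responseShift        = shift,
    molecularShift       = molecularShift,
    tensorRank           = as.integer(tensorRank),
    tensorClassEffect    = as.numeric(tensorClassEffect),
    noiseSd              = defaults,
    missingRate          = as.numeric(missingRate),
    seed                 = as.integer(seed)
  )
}

#' Read a generator configuration from YAML or JSON
#'
#' Field names mirror [simConfig()] arguments; `snake_case` keys
#' (`n_subjects`, `missing_rate`, ...) are accepted as aliases.
#'
#' @param path path to a YAML (or JSON) file.
#' @return A [SimConfig-class] object.
#' @export
simConfigFromFile <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  snake2camel <- function(x)
    gsub("_(\\w)", "\\U\\1", x, perl = TRUE)
  names(raw) <- snake2camel(names(raw))
  if (!is.null(raw$responseShift) && is.list(raw$responseShift))
    raw$responseShift <- do.call(rbind, raw$responseShift)
  do.call(simConfig, raw)
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d subjects, %d classes, seed %d\n",
    object@nSubjects, object@nClasses, object@seed))
  cat(sprintf(
    "  blocks: microbiota %d | scfa %d x 2 | metabolome %d | clinical %d+%d\n",
    object@nGenera, object@nScfa, object@nMetabolomeFeatures,
    object@nClinicalContinuous, object@nClinicalCategorical))
  cat(sprintf("  tensor: rank %d, %d timepoints, %.0f%% missing\n",
              object@tensorRank, length(object@timepoints),
              100 * object@missingRate))
})

## Per-block RNG streams ------------------------------------------------------
## Each named stream is seeded deterministically from the master seed so that
## resizing one block never perturbs another (seed-isolation contract).
.STREAM_OFFSETS <- c(
  classes = 101L, sss = 211L, microbiota = 307L, scfa = 401L,
  metabolome = 503L, clinical = 601L, tensor = 701L, mask = 811L,
  downsample = 907L, rdcv = 1009L, perm = 1103L, pipeline = 1201L
)

.streamSeed <- function(seed, stream) {
  off <- .STREAM_OFFSETS[[stream]]
  as.integer((as.numeric(seed) * 7919 + off * 104729) %% 2147483647)
}

.withStream <- function(seed, stream, code) {
  withr::with_seed(.streamSeed(seed, stream), code)
}
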