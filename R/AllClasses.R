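#' @include AllGenerics.R
NULL

## Fixed vocabulary of the three-arm crossover design ------------------------

#' Design vocabulary
#'
#' The three intervention arms, the five IBS-SSS items, the response
#' representations and the blood-draw schedule of the rapid provocation test.
#' These are constants of the study design the package models.
#'
#' @name designVocabulary
#' @aliases trialArms sssItems responseItems responseRepresentations
#'   provocationMinutes
NULL

#' @rdname designVocabulary
#' @export
trialArms <- function() c("FODMAP", "gluten", "placebo")

#' @rdname designVocabulary
#' @export
sssItems <- function() {
  c("pain_severity", "pain_frequency", "distension",
    "bowel_dissatisfaction", "life_interference")
}

#' @rdname designVocabulary
#' @export
responseItems <- function() c(sssItems(), "total")

#' @rdname designVocabulary
#' @export
responseRepresentations <- function() c("absolute", "difference", "lfc")

#' @rdname designVocabulary
#' @export
provocationMinutes <- function() c(-10, 0, 10, 20, 30, 90, 150, 240)

.WEEK_TYPES <- c("intervention", "washout")

## TrialDataset ---------------------------------------------------------------

#' TrialDataset: a complete three-arm crossover trial
#'
#' Per-subject records of a three-arm (FODMAP, gluten, placebo) crossover
#' provocation trial: IBS-SSS item scores for each intervention week and its
#' preceding washout week, baseline molecular blocks (genus-level microbiota
#' relative abundances, fecal and plasma SCFA concentrations, untargeted
#' plasma metabolome intensities), a mixed clinical/questionnaire table, and
#' — for synthetic data only — the hidden ground-truth metabotype label of
#' each subject.
#'
#' @slot subjectIds character vector of subject identifiers.
#' @slot sss numeric array `subjects x 3 arms x 2 week types x 5 items` of
#'   IBS-SSS item scores, each in \[0, 100\].
#' @slot blocks named list of numeric matrices (subjects in rows):
#'   `microbiota` (rows sum to 1), `fecal_scfa`, `plasma_scfa`,
#'   `metabolome` (positive intensities).
#' @slot clinical data.frame of baseline clinical/questionnaire variables
#'   (continuous and factor columns).
#' @slot trueClass integer vector of hidden class labels (synthetic data
#'   only; length 0 for real data).
#' @slot groundTruth list of generator internals (shifted features, planted
#'   effects); empty for real data.
#'
#' @seealso [simulateTrial()], [condenseResponseFrame()]
#' @export
setClass("TrialDataset",
  representation(
    subjectIds  = "character",
    sss         = "array",
    blocks      = "list",
    clinical    = "data.frame",
    trueClass   = "integer",
    groundTruth = "list"
  )
)

setValidity("TrialDataset", function(object) {
  n <- length(object@subjectIds)
  msg <- character()
  d <- dim(object@sss)
  if (length(d) != 4L || d[1] != n || d[2] != 3L || d[3] != 2L || d[4] != 5L)
    msg <- c(msg, "sss must be an n x 3 x 2 x 5 array")
  if (any(object@sss < 0 | object@sss > 100))
    msg <- c(msg, "all IBS-SSS item scores must lie in [0, 100]")
  for (b in names(object@blocks)) {
    if (nrow(object@blocks[[b]]) != n)
      msg <- c(msg, sprintf("block '%s' must have one row per subject", b))
  }
  if ("microbiota" %in% names(object@blocks)) {
    rs <- rowSums(object@blocks[["microbiota"]])
    if (any(abs(rs - 1) > 1e-9))
      msg <- c(msg, "microbiota rows must sum to 1 within 1e-9")
  }
  if (length(object@trueClass) && length(object@trueClass) != n)
    msg <- c(msg, "trueClass must be empty or one label per subject")
  if (nrow(object@clinical) && nrow(object@clinical) != n)
    msg <- c(msg, "clinical table must have one row per subject")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
setMethod("subjectIds", "TrialDataset", function(x) x@subjectIds)

#' @rdname accessors
setMethod("trueClass", "TrialDataset", function(x) x@trueClass)

#' @rdname accessors
setMethod("blockNames", "TrialDataset", function(x) names(x@blocks))

#' @rdname accessors
setMethod("baselineBlock", "TrialDataset", function(x, name) {
  if (!name %in% names(x@blocks))
    stop("unknown block: ", name, call. = FALSE)
  x@blocks[[name]]
})

#' @rdname accessors
setMethod("clinicalData", "TrialDataset", function(x) x@clinical)

#' @rdname accessors
setMethod("sssScores", "TrialDataset", function(x) x@sss)

setMethod("show", "TrialDataset", function(object) {
  cat("TrialDataset with", length(object@subjectIds), "subjects\n")
  cat("  arms:", paste(trialArms(), collapse = ", "), "\n")
  dims <- vapply(object@blocks, ncol, integer(1))
  cat("  blocks:",
      paste(sprintf("%s (%d)", names(dims), dims), collapse = ", "), "\n")
  cat("  clinical variables:", ncol(object@clinical), "\n")
  if (length(object@trueClass))
    cat("  hidden classes:",
        paste(sort(unique(object@trueClass)), collapse = ", "), "\n")
})

## ProvocationTensor ----------------------------------------------------------

#' ProvocationTensor: subjects x features x timepoints metabolome array
#'
#' Metabolite-feature intensities measured over the blood-draw schedule of a
#' rapid provocation test (minutes -10, 0, 10, 20, 30, 90, 150, 240 by
#' default), with a logical missing-value mask.
#'
#' @slot values numeric array `subjects x features x timepoints`; masked
#'   cells hold `NA`.
#' @slot mask logical array, same shape, `TRUE` where the cell is missing.
#' @slot minutes numeric, strictly increasing timepoint coordinates (min).
#' @slot subjectIds,featureIds identifiers for the first two modes.
#' @slot groundTruth list of generator factors (synthetic data only).
#'
#' @seealso [simulateProvocationTensor()], [imputeTensor()], [parafacALS()]
#' @export
setClass("ProvocationTensor",
  representation(
    values      = "array",
    mask        = "array",
    minutes     = "numeric",
    subjectIds  = "character",
    featureIds  = "character",
    groundTruth = "list"
  )
)

setValidity("ProvocationTensor", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (length(d) != 3L)
    msg <- c(msg, "values must be a 3-way array")
  if (!identical(dim(object@mask), d))
    msg <- c(msg, "mask and values must be congruent in shape")
  if (length(object@minutes) != d[3])
    msg <- c(msg, "one minute coordinate per timepoint required")
  if (is.unsorted(object@minutes, strictly = TRUE))
    msg <- c(msg, "minutes must be strictly increasing")
  if (length(object@subjectIds) != d[1])
    msg <- c(msg, "one subject id per slice required")
  if (length(object@featureIds) != d[2])
    msg <- c(msg, "one feature id per column required")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
setMethod("subjectIds", "ProvocationTensor", function(x) x@subjectIds)

#' @rdname accessors
setMethod("tensorValues", "ProvocationTensor", function(x) x@values)

#' @rdname accessors
setMethod("missingMask", "ProvocationTensor", function(x) x@mask)

#' @rdname accessors
setMethod("timeMinutes", "ProvocationTensor", function(x) x@minutes)

setMethod("show", "ProvocationTensor", function(object) {
  d <- dim(object@values)
  cat(sprintf("ProvocationTensor: %d subjects x %d features x %d timepoints\n",
              d[1], d[2], d[3]))
  cat("  minutes:", paste(object@minutes, collapse = ", "), "\n")
  cat(sprintf("  missing cells: %d (%.1f%%)\n", sum(object@mask),
              100 * mean(object@mask)))
})

## ResponseFrame --------------------------------------------------------------

#' ResponseFrame: one response variable condensed across the three arms
#'
#' A subjects x 3 matrix holding one IBS-SSS variable (an item or the total
#' score) under one representation (absolute, difference vs the preceding
#' washout week, or log2 fold change), one column per intervention arm.
#'
#' @slot values numeric matrix, subjects in rows, arms in columns.
#' @slot item which IBS-SSS variable (see [responseItems()]).
#' @slot representation one of `absolute`, `difference`, `lfc`.
#'
#' @seealso [condenseResponseFrame()], [clusterResponses()]
#' @export
setClass("ResponseFrame",
  representation(
    values         = "matrix",
    item           = "character",
    representation = "character"
  )
)

setValidity("ResponseFrame", function(object) {
  msg <- character()
  if (ncol(object@values) != 3L)
    msg <- c(msg, "values must have one column per arm")
  if (any(colSums(!is.na(object@values)) == 0))
    msg <- c(msg, "no arm column may be entirely missing")
  if (!object@item %in% responseItems())
    msg <- c(msg, "unknown IBS-SSS item")
  if (!object@representation %in% responseRepresentations())
    msg <- c(msg, "unknown representation")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
setMethod("responseValues", "ResponseFrame", function(x) x@values)

#' @rdname accessors
setMethod("subjectIds", "ResponseFrame", function(x) rownames(x@values))

#' @rdname accessors
setMethod("provenance", "ResponseFrame", function(x)
  list(item = x@item, representation = x@representation))

setMethod("show", "ResponseFrame", function(object) {
  cat(sprintf("ResponseFrame: %d subjects x 3 arms (%s, %s)\n",
              nrow(object@values), object@item, object@representation))
})

## ClusterAssignment ----------------------------------------------------------

#' ClusterAssignment: a candidate metabotype partition
#'
#' Subject labels from one cell of the clustering grid, together with the
#' provenance needed to reproduce it (item, representation, method, k,
#' scaling).
#'
#' @slot labels integer vector of labels in `1..k`, named by subject id.
#' @slot provenance list with entries `item`, `representation`, `method`
#'   (`hierarchical` or `kmeans`), `k`, `scaled`.
#'
#' @seealso [clusterResponses()], [filterMinSize()], [downsampleBalanced()]
#' @export
setClass("ClusterAssignment",
  representation(
    labels     = "integer",
    provenance = "list"
  )
)

setValidity("ClusterAssignment", function(object) {
  msg <- character()
  lab <- object@labels
  if (!length(lab)) msg <- c(msg, "empty assignment")
  u <- sort(unique(lab))
  if (length(u) && !identical(u, seq_along(u)))
    msg <- c(msg, "labels must be contiguous from 1")
  if (is.null(names(lab)))
    msg <- c(msg, "labels must be named by subject id")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
setMethod("clusterLabels", "ClusterAssignment", function(x) x@labels)

#' @rdname accessors
setMethod("clusterSizes", "ClusterAssignment", function(x)
  as.integer(table(x@labels)))

#' @rdname accessors
setMethod("provenance", "ClusterAssignment", function(x) x@provenance)

#' @rdname accessors
setMethod("subjectIds", "ClusterAssignment", function(x) names(x@labels))

setMethod("show", "ClusterAssignment", function(object) {
  pv <- object@provenance
  cat(sprintf("ClusterAssignment: k = %d (%s, %s, %s, %s)\n",
              max(object@labels), pv$method,
              if (isTRUE(pv$scaled)) "scaled" else "non-scaled",
              pv$item, pv$representation))
  cat("  sizes:", paste(clusterSizes(object), collapse = ", "), "\n")
})

## RdcvResult -----------------------------------------------------------------

#' RdcvResult: outcome of one repeated double cross-validated screen
#'
#' Out-of-fold fitness (Q2 for regression, classification rate CR for
#' classification) of a repeated double cross-validated random-forest model,
#' with per-repetition values, out-of-fold predictions, and the selected
#' variable ladder (min/mid/max counts).
#'
#' @slot task `regression` or `classification`.
#' @slot fitness mean out-of-fold fitness over repetitions.
#' @slot perRepetition numeric, fitness of each repetition.
#' @slot outOfFold matrix of out-of-fold predictions, subjects x repetitions.
#' @slot selected list with `nMin`, `nMid`, `nMax` (variable counts) and
#'   `variables` (names at the mid count), empty when selection is off.
#' @slot thresholdPass `TRUE` when the a priori screen filter is met
#'   (Q2 > 0.2 or CR > 0.6).
#'
#' @seealso [rdcvFit()], [permutationTest()]
#' @export
setClass("RdcvResult",
  representation(
    task          = "character",
    fitness       = "numeric",
    perRepetition = "numeric",
    outOfFold     = "matrix",
    selected      = "list",
    thresholdPass = "logical"
  )
)

#' @rdname accessors
setMethod("fitness", "RdcvResult", function(x) x@fitness)

#' @rdname accessors
setMethod("perRepetitionFitness", "RdcvResult", function(x) x@perRepetition)

#' @rdname accessors
setMethod("thresholdPass", "RdcvResult", function(x) x@thresholdPass)

#' @rdname accessors
setMethod("selectedVariables", "RdcvResult", function(x) x@selected)

setMethod("show", "RdcvResult", function(object) {
  metric <- if (object@task == "regression") "Q2" else "CR"
  cat(sprintf("RdcvResult (%s): %s = %.3f over %d repetitions%s\n",
              object@task, metric, object@fitness,
              length(object@perRepetition),
              if (object@thresholdPass) " [passes a priori filter]" else ""))
  if (length(object@selected))
    cat(sprintf("  selected variables (min/mid/max): %d/%d/%d\n",
                object@selected$nMin, object@selected$nMid,
                object@selected$nMax))
})

## ParafacModel ---------------------------------------------------------------

#' ParafacModel: a trilinear (PARAFAC) decomposition
#'
#' Factor matrices of a C-component PARAFAC model of a subjects x features x
#' timepoints tensor, fitted by alternating least squares. Feature (`B`) and
#' time (`D`) loadings are unit-norm with component magnitude carried in the
#' subject scores (`A`); the largest-magnitude element of each time loading
#' is positive; components are ordered by decreasing magnitude.
#'
#' @slot A subject scores, n x C.
#' @slot B feature loadings, p x C, unit-norm columns.
#' @slot D time loadings, t x C, unit-norm columns.
#' @slot fit fraction of the preprocessed sum of squares explained.
#' @slot iterations number of ALS iterations run.
#' @slot converged `TRUE` when the relative SSE change fell below tolerance.
#' @slot sseTrace per-iteration residual sum of squares (monotone
#'   non-increasing).
#'
#' @seealso [parafacALS()], [tuckerCongruence()], [linkageScreen()]
#' @export
setClass("ParafacModel",
  representation(
    A          = "matrix",
    B          = "matrix",
    D          = "matrix",
    fit        = "numeric",
    iterations = "integer",
    converged  = "logical",
    sseTrace   = "numeric"
  )
)

setValidity("ParafacModel", function(object) {
  msg <- character()
  C <- ncol(object@A)
  if (ncol(object@B) != C || ncol(object@D) != C)
    msg <- c(msg, "factor matrices must share the component count")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
setMethod("subjectScores", "ParafacModel", function(x) x@A)

#' @rdname accessors
setMethod("featureLoadings", "ParafacModel", function(x) x@B)

#' @rdname accessors
setMethod("timeLoadings", "ParafacModel", function(x) x@D)

#' @rdname accessors
setMethod("modelFit", "ParafacModel", function(x) x@fit)

#' @rdname accessors
setMethod("isConverged", "ParafacModel", function(x) x@converged)

setMethod("show", "ParafacModel", function(object) {
  cat(sprintf("ParafacModel: %d components, fit = %.4f (%d iterations%s)\n",
              ncol(object@A), object@fit, object@iterations,
              if (object@converged) ", converged" else ", NOT converged"))
})
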