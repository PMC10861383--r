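#' @include AllGenerics.R
NULL

#' Accessor generics
#'
#' Small accessor generics shared by the package's S4 containers. Using
#' accessors (rather than `@` slot access) keeps the internal representation
#' free to change.
#'
#' @param x An object of one of the package's S4 classes.
#' @param ... Further arguments passed to methods.
#' @return The slot contents; see the individual class pages.
#' @name accessors
#' @aliases subjectIds trueClass blockNames baselineBlock clinicalData
#'   sssScores tensorValues missingMask timeMinutes clusterLabels
#'   clusterSizes provenance responseValues fitness perRepetitionFitness
#'   thresholdPass selectedVariables subjectScores featureLoadings
#'   timeLoadings modelFit isConverged
NULL

#' @rdname accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname accessors
#' @export
setGeneric("trueClass", function(x) standardGeneric("trueClass"))

#' @rdname accessors
#' @export
setGeneric("blockNames", function(x) standardGeneric("blockNames"))

#' @rdname accessors
#' @export
setGeneric("baselineBlock", function(x, name) standardGeneric("baselineBlock"))

#' @rdname accessors
#' @export
setGeneric("clinicalData", function(x) standardGeneric("clinicalData"))

#' @rdname accessors
#' @export
setGeneric("sssScores", function(x) standardGeneric("sssScores"))

#' @rdname accessors
#' @export
setGeneric("tensorValues", function(x) standardGeneric("tensorValues"))

#' @rdname accessors
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @rdname accessors
#' @export
setGeneric("timeMinutes", function(x) standardGeneric("timeMinutes"))

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setGeneric("clusterSizes", function(x) standardGeneric("clusterSizes"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("responseValues", function(x) standardGeneric("responseValues"))

#' @rdname accessors
#' @export
setGeneric("fitness", function(x) standardGeneric("fitness"))

#' @rdname accessors
#' @export
setGeneric("perRepetitionFitness", function(x)
  standardGeneric("perRepetitionFitness"))

#' @rdname accessors
#' @export
setGeneric("thresholdPass", function(x) standardGeneric("thresholdPass"))

#' @rdname accessors
#' @export
setGeneric("selectedVariables", function(x)
  standardGeneric("selectedVariables"))

#' @rdname accessors
#' @export
setGeneric("subjectScores", function(x) standardGeneric("subjectScores"))

#' @rdname accessors
#' @export
setGeneric("featureLoadings", function(x) standardGeneric("featureLoadings"))

#' @rdname accessors
#' @export
setGeneric("timeLoadings", function(x) standardGeneric("timeLoadings"))

#' @rdname accessors
#' @export
setGeneric("modelFit", function(x) standardGeneric("modelFit"))

#' @rdname accessors
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))
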