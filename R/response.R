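#' @include io.R
NULL

#' Total IBS-SSS score
#'
#' Sum of the five visual-analog items (each 0--100), giving the composite
#' total on the 0--500 scale.
#'
#' @param items numeric vector of 5 item scores, or a matrix with 5 columns
#'   (one row per record).
#' @return numeric total score(s).
#' @examples
#' totalScore(c(50, 40, 30, 20, 10))  # 150
#' @export
totalScore <- function(items) {
  m <- if (is.matrix(items)) items else matrix(items, nrow = 1)
  if (ncol(m) != 5L)
    stop("exactly five item scores required", call. = FALSE)
  if (any(m < 0 | m > 100, na.rm = TRUE))
    stop("item scores must lie in [0, 100]", call. = FALSE)
  tot <- rowSums(m)
  if (!is.matrix(items)) tot <- unname(tot)
  tot
}

#' IBS severity category
#'
#' Total score < 175 is mild, 175 to 300 (inclusive) moderate, > 300 severe.
#'
#' @param total total score(s) on the 0--500 scale.
#' @return factor with levels `mild`, `moderate`, `severe`.
#' @examples
#' severityCategory(c(174, 175, 300, 301))
#' @export
severityCategory <- function(total) {
  if (any(total < 0 | total > 500, na.rm = TRUE))
    stop("total score must lie in [0, 500]", call. = FALSE)
  ## the moderate band is closed on both ends: 175 and 300 are moderate
  factor(ifelse(total < 175, "mild",
         ifelse(total <= 300, "moderate", "severe")),
         levels = c("mild", "moderate", "severe"))
}

#' Represent a response value against the preceding washout week
#'
#' The three response representations used throughout the screens:
#' `absolute` returns the intervention-week value; `difference` the change
#' versus the preceding washout week; `lfc` the log2 fold change with an
#' additive guard of 1 on both scores (so 0 vs 0 gives 0).
#'
#' @param intervention,washout numeric scores (vectorized).
#' @param mode one of [responseRepresentations()].
#' @return numeric response value(s).
#' @examples
#' representResponse(240, 198, "difference")  # 42
#' @export
representResponse <- function(intervention, washout,
                              mode = c("absolute", "difference", "lfc")) {
  mode <- match.arg(mode)
  if (any(intervention < 0, na.rm = TRUE) || any(washout < 0, na.rm = TRUE))
    stop("scores must be non-negative", call. = FALSE)
  switch(mode,
    absolute   = intervention,
    difference = intervention - washout,
    lfc        = log2((intervention + 1) / (washout + 1)))
}

#' Clinically significant symptom increase
#'
#' `TRUE` when the intervention week exceeds the preceding washout week by
#' strictly more than 50 points on the total IBS-SSS scale, the conventional
#' threshold for a clinically significant effect.
#'
#' @param intervention,washout total scores (vectorized).
#' @return logical flag(s).
#' @examples
#' clinicallySignificant(251, 200)  # TRUE
#' clinicallySignificant(250, 200)  # FALSE
#' @export
clinicallySignificant <- function(intervention, washout) {
  (intervention - washout) > 50
}

#' Condense one response variable across the three arms
#'
#' Builds the subjects x 3 [ResponseFrame-class] screened downstream: the
#' chosen IBS-SSS variable (item or total) under the chosen representation,
#' one column per intervention arm, each computed against that arm's
#' preceding washout week. Subjects missing any arm are excluded with a
#' warning.
#'
#' @param dataset a [TrialDataset-class].
#' @param item one of [responseItems()].
#' @param representation one of [responseRepresentations()].
#' @return A [ResponseFrame-class].
#' @examples
#' ds <- simulateTrial(simConfig(nSubjects = 10, nMetabolomeFeatures = 20))
#' condenseResponseFrame(ds, "total", "difference")
#' @export
condenseResponseFrame <- function(dataset, item = responseItems(),
                                  representation = responseRepresentations()) {
  item <- match.arg(item)
  representation <- match.arg(representation)
  arr <- sssScores(dataset)
  score <- function(arm, week) {
    m <- arr[, arm, week, , drop = FALSE]
    m <- matrix(m, nrow = dim(arr)[1], ncol = 5L)
    if (item == "total") rowSums(m) else m[, match(item, sssItems())]
  }
  vals <- sapply(trialArms(), function(a)
    representResponse(score(a, "intervention"), score(a, "washout"),
                      representation))
  vals <- matrix(vals, ncol = 3L,
                 dimnames = list(subjectIds(dataset), trialArms()))
  keep <- stats::complete.cases(vals)
  if (!all(keep)) {
    warning(sum(!keep), " subject(s) missing an arm excluded from the ",
            "response frame", call. = FALSE)
    vals <- vals[keep, , drop = FALSE]
  }
  methods::new("ResponseFrame", values = vals, item = item,
               representation = representation)
}
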