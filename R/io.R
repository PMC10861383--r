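#' @include synth-tensor.R
NULL

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' IBS-SSS scores in long format
#'
#' One row per subject x arm x week type x item, the exchange format used
#' by the writers and accepted back by [sssArrayFromLong()].
#'
#' @param dataset a [TrialDataset-class].
#' @return data.frame with columns `subject`, `arm`,
#'   `week_type` (`intervention`/`washout`), `item`, `score`.
#' @export
sssLong <- function(dataset) {
  arr <- sssScores(dataset)
  dn <- dimnames(arr)
  g <- expand.grid(subject = dn[[1]], arm = dn[[2]], week_type = dn[[3]],
                   item = dn[[4]], KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  g$score <- as.vector(arr)
  g[order(g$subject, g$arm, g$week_type, g$item), , drop = FALSE]
}

#' Rebuild the IBS-SSS array from long format
#'
#' @param df a data.frame with the columns written by [sssLong()] (e.g. read
#'   from a user's TSV).
#' @return numeric array `subjects x arms x week types x items`.
#' @export
sssArrayFromLong <- function(df) {
  need <- c("subject", "arm", "week_type", "item", "score")
  if (!all(need %in% names(df)))
    stop("long IBS-SSS table needs columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  subj <- sort(unique(df$subject))
  arr <- array(NA_real_,
               dim = c(length(subj), 3L, 2L, 5L),
               dimnames = list(subj, trialArms(), .WEEK_TYPES, sssItems()))
  idx <- cbind(match(df$subject, subj), match(df$arm, trialArms()),
               match(df$week_type, .WEEK_TYPES), match(df$item, sssItems()))
  arr[idx] <- df$score
  arr
}

#' Write a trial dataset to plain-text files
#'
#' Emits one TSV per baseline block (subjects in rows, feature names in the
#' header), the IBS-SSS scores in long format, the clinical table, and a
#' JSON sidecar with the generator's ground truth (hidden class labels and
#' planted effects) when present.
#'
#' @param dataset a [TrialDataset-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeTrialDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (b in blockNames(dataset)) {
    m <- baselineBlock(dataset, b)
    df <- data.frame(subject = rownames(m), m, check.names = FALSE)
    p <- file.path(dir, paste0(b, ".tsv"))
    .writeTsv(df, p)
    paths <- c(paths, p)
  }
  cl <- clinicalData(dataset)
  p <- file.path(dir, "clinical.tsv")
  .writeTsv(data.frame(subject = rownames(cl), cl, check.names = FALSE), p)
  paths <- c(paths, p)
  p <- file.path(dir, "ibs_sss_long.tsv")
  .writeTsv(sssLong(dataset), p)
  paths <- c(paths, p)
  if (length(trueClass(dataset))) {
    p <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(
      list(true_class = stats::setNames(as.list(trueClass(dataset)),
                                        subjectIds(dataset)),
           ground_truth = dataset@groundTruth),
      p, auto_unbox = TRUE, digits = NA, force = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write a provocation tensor to plain-text files
#'
#' Observed cells go to a 3-column-indexed long TSV (`subject`, `feature`,
#' `minute`, `intensity`), masked cells to a companion missing-cell list,
#' and the generator's factor matrices to a JSON sidecar when present.
#'
#' @param tensor a [ProvocationTensor-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeProvocationTensor <- function(tensor, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vals <- tensorValues(tensor)
  mask <- missingMask(tensor)
  g <- expand.grid(subject = tensor@subjectIds,
                   feature = tensor@featureIds,
                   minute = timeMinutes(tensor),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$intensity <- as.vector(vals)
  obs <- g[!as.vector(mask), , drop = FALSE]
  p1 <- file.path(dir, "provocation_tensor.tsv")
  .writeTsv(obs, p1)
  p2 <- file.path(dir, "provocation_missing.tsv")
  .writeTsv(g[as.vector(mask), c("subject", "feature", "minute")], p2)
  paths <- c(p1, p2)
  if (length(tensor@groundTruth)) {
    p3 <- file.path(dir, "tensor_ground_truth.json")
    jsonlite::write_json(tensor@groundTruth, p3, digits = NA, force = TRUE)
    paths <- c(paths, p3)
  }
  invisible(paths)
}

#' Write a cluster assignment
#'
#' Labels as a two-column TSV plus a JSON provenance record.
#'
#' @param assignment a [ClusterAssignment-class].
#' @param dir output directory.
#' @param stem file stem (default `"assignment"`).
#' @return Invisibly, the paths written.
#' @export
writeClusterAssignment <- function(assignment, dir, stem = "assignment") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lab <- clusterLabels(assignment)
  p1 <- file.path(dir, paste0(stem, ".tsv"))
  .writeTsv(data.frame(subject_id = names(lab), label = as.integer(lab)), p1)
  p2 <- file.path(dir, paste0(stem, ".json"))
  jsonlite::write_json(provenance(assignment), p2, auto_unbox = TRUE)
  invisible(c(p1, p2))
}
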