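#' @include response.R
NULL

#' Cluster subjects on a condensed response frame
#'
#' Partitions subjects into `k` candidate metabotypes from their response
#' pattern across the three arms, with the two methods of the screening
#' grid: hierarchical clustering (Euclidean distance, complete linkage,
#' tree cut at `k`) or k-means (Lloyd updates, 25 random restarts, best
#' within-cluster sum of squares). With `scaled = TRUE` columns are
#' z-scored first; constant columns are dropped with a warning. Labels are
#' renumbered contiguously in order of first appearance, so results are
#' deterministic under a fixed seed.
#'
#' @param frame a [ResponseFrame-class].
#' @param method `hierarchical` or `kmeans`.
#' @param k number of clusters, 2--4.
#' @param scaled z-score columns first?
#' @param seed RNG seed (k-means restarts).
#' @param nstart k-means restarts (default 25).
#' @return A [ClusterAssignment-class] with full provenance.
#' @export
clusterResponses <- function(frame, method = c("hierarchical", "kmeans"),
                             k, scaled = FALSE, seed = 1L, nstart = 25L) {
  method <- match.arg(method)
  if (!k %in% 2:4)
    stop("k must be 2, 3 or 4", call. = FALSE)
  x <- responseValues(frame)
  if (nrow(unique(x)) < k)
    stop("fewer distinct response rows than clusters requested",
         call. = FALSE)
  if (scaled) {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) {
      warning("constant column(s) dropped under scaling: ",
              paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
      x <- x[, sds > 0, drop = FALSE]
      sds <- sds[sds > 0]
    }
    x <- scale(x)
  }
  lab <- if (method == "hierarchical") {
    stats::cutree(stats::hclust(stats::dist(x), method = "complete"), k = k)
  } else {
    withr::with_seed(as.integer(seed),
      stats::kmeans(x, centers = k, nstart = nstart,
                    algorithm = "Lloyd", iter.max = 100L)$cluster)
  }
  ## contiguous labels in order of first appearance (reproducible naming)
  lab <- as.integer(factor(lab, levels = unique(lab)))
  names(lab) <- rownames(responseValues(frame))
  pv <- provenance(frame)
  methods::new("ClusterAssignment", labels = lab,
               provenance = list(item = pv$item,
                                 representation = pv$representation,
                                 method = method, k = as.integer(k),
                                 scaled = scaled, seed = as.integer(seed)))
}

#' Minimum-cluster-size filter
#'
#' A clustering solution is eligible for classification screening only when
#' every cluster holds at least `minN` participants (default 8).
#'
#' @param assignment a [ClusterAssignment-class].
#' @param minN minimum participants per cluster.
#' @return `TRUE` when all cluster sizes are at least `minN`.
#' @examples
#' ## sizes (8, 8) pass; (10, 7) fail
#' @export
filterMinSize <- function(assignment, minN = 8L) {
  all(clusterSizes(assignment) >= minN)
}

#' Balanced random downsampling of clusters
#'
#' To avoid biasing classification towards the majority class, every
#' cluster is represented by exactly `min(sizes)` subjects, sampled without
#' replacement under the given seed.
#'
#' @param assignment a [ClusterAssignment-class] that passed
#'   [filterMinSize()].
#' @param seed RNG seed.
#' @return character vector of retained subject ids (sorted by original
#'   order).
#' @export
downsampleBalanced <- function(assignment, seed = 1L) {
  lab <- clusterLabels(assignment)
  target <- min(clusterSizes(assignment))
  keep <- withr::with_seed(as.integer(seed), {
    unlist(lapply(sort(unique(lab)), function(g) {
      ids <- names(lab)[lab == g]
      if (length(ids) == target) ids else sample(ids, target)
    }), use.names = FALSE)
  })
  names(lab)[names(lab) %in% keep]
}

#' Enumerate the response clustering grid
#'
#' The full grid over one dataset: 6 IBS-SSS variables x 3 representations
#' x 2 methods x 2 scalings x 3 k-values = 216 candidate assignments.
#'
#' @return data.frame with one row per grid cell (columns `item`,
#'   `representation`, `method`, `scaled`, `k`), in deterministic
#'   lexicographic order.
#' @export
enumerateAssignmentGrid <- function() {
  g <- expand.grid(k = 2:4, scaled = c(FALSE, TRUE),
                   method = c("hierarchical", "kmeans"),
                   representation = responseRepresentations(),
                   item = responseItems(),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g[, c("item", "representation", "method", "scaled", "k")]
}
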