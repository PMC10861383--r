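#' @include parafac-als.R
NULL

## 1-d clustering of a component score vector, same settings as the
## response-frame grid (Euclidean/complete or Lloyd k-means, 25 restarts).
.clusterVector <- function(x, method, k, scaled, seed = 1L, nstart = 25L) {
  v <- as.numeric(x)
  if (scaled && stats::sd(v) > 0) v <- as.numeric(scale(v))
  m <- matrix(v, ncol = 1)
  lab <- if (method == "hierarchical") {
    stats::cutree(stats::hclust(stats::dist(m), method = "complete"), k = k)
  } else {
    withr::with_seed(as.integer(seed),
      stats::kmeans(m, centers = k, nstart = nstart,
                    algorithm = "Lloyd", iter.max = 100L)$cluster)
  }
  as.integer(factor(lab, levels = unique(lab)))
}

#' Enumerate the PARAFAC linkage screen
#'
#' For one clustering approach (method x scaling), every component score
#' vector of every model (sum of C over C = 2..20 is 209 vectors) is
#' clustered at k = 2, 3, 4 and linked by one-way ANOVA to each of the 6
#' IBS-SSS variables in each of the 3 arms: 209 x 3 x 3 x 6 = 11,286
#' candidate models.
#'
#' @param componentRange model sizes fitted (default `2:20`).
#' @param kValues cluster counts (default `2:4`).
#' @return data.frame with one row per candidate linkage model.
#' @examples
#' nrow(enumerateLinkageScreen())  # 11286
#' @export
enumerateLinkageScreen <- function(componentRange = 2:20, kValues = 2:4) {
  comp <- do.call(rbind, lapply(componentRange, function(C)
    data.frame(nComponents = C, component = seq_len(C))))
  g <- merge(comp,
             expand.grid(k = kValues, arm = trialArms(),
                         item = responseItems(),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE),
             by = NULL)
  g <- g[order(g$nComponents, g$component, g$k, g$arm, g$item), ]
  rownames(g) <- NULL
  g
}

#' ANOVA linkage of PARAFAC score clusters to IBS symptoms
#'
#' For each fitted model's component score vectors: cluster at each k with
#' the given approach, flag solutions violating the minimum cluster size
#' (results are retained but marked ineligible), and run a one-way ANOVA
#' of every IBS-SSS variable (absolute values) in every arm across the
#' clusters.
#'
#' @param models list of [ParafacModel-class], one per component count.
#' @param dataset the [TrialDataset-class] providing the symptom scores.
#' @param method,scaled the clustering approach (one of the four
#'   method x scaling combinations).
#' @param kValues cluster counts (default `2:4`).
#' @param minN minimum participants per cluster for eligibility (default
#'   8).
#' @param seed RNG seed for k-means restarts.
#' @return data.frame: one row per candidate model with cluster sizes,
#'   eligibility, F statistic and p value.
#' @export
linkageScreen <- function(models, dataset,
                          method = c("hierarchical", "kmeans"),
                          scaled = FALSE, kValues = 2:4, minN = 8L,
                          seed = 1L) {
  method <- match.arg(method)
  arms <- trialArms()
  items <- responseItems()
  frames <- lapply(items, function(it)
    responseValues(condenseResponseFrame(dataset, it, "absolute")))
  names(frames) <- items
  rows <- list()
  for (model in models) {
    A <- subjectScores(model)
    C <- ncol(A)
    for (cc in seq_len(C)) {
      for (k in kValues) {
        lab <- .clusterVector(A[, cc], method, k, scaled, seed = seed)
        sizes <- as.integer(table(lab))
        eligible <- all(sizes >= minN)
        anovaOk <- all(sizes >= 2L)
        for (arm in arms) {
          for (it in items) {
            y <- frames[[it]][, arm]
            ft <- if (anovaOk) onewayAnova(y, lab)
                  else list(F = NA_real_, p = NA_real_)
            rows[[length(rows) + 1L]] <- data.frame(
              nComponents = C, component = cc, method = method,
              scaled = scaled, k = k,
              minSize = min(sizes), eligible = eligible,
              arm = arm, item = it, F = ft$F, p = ft$p)
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-arm enrichment of nominally significant linkage models
#'
#' Counts eligible linkage models with p below `alpha` per arm and tests
#' homogeneity of the counts against an equal expectation with a
#' chi-square goodness-of-fit test. Equal spread across the active arms
#' and placebo argues against treatment-specific metabotype structure.
#'
#' @param results output of [linkageScreen()] (one clustering approach).
#' @param alpha nominal significance level (default 0.05).
#' @param eligibleOnly restrict to models meeting the minimum-size
#'   requirement (default `TRUE`).
#' @return list with `counts` (named per arm), `total`, and `homogeneity`
#'   (`statistic`, `df`, `p`; `NA` when no model is significant).
#' @export
enrichmentSummary <- function(results, alpha = 0.05, eligibleOnly = TRUE) {
  r <- results
  if (eligibleOnly) r <- r[r$eligible, , drop = FALSE]
  counts <- vapply(trialArms(), function(a)
    sum(r$p[r$arm == a] < alpha, na.rm = TRUE), numeric(1))
  total <- sum(counts)
  homo <- if (total > 0) {
    stat <- sum((counts - total / 3)^2 / (total / 3))
    list(statistic = stat, df = 2L,
         p = stats::pchisq(stat, df = 2L, lower.tail = FALSE))
  } else list(statistic = NA_real_, df = 2L, p = NA_real_)
  list(counts = counts, total = total, homogeneity = homo)
}

#' Co-clustering frequency of subjects across linkage models
#'
#' How often each subject pair lands in the same cluster across the score
#' clusterings of a model list — the summary used to look for reproducibly
#' clustered participants.
#'
#' @param models list of [ParafacModel-class].
#' @param method,scaled,kValues,seed as in [linkageScreen()].
#' @return symmetric matrix of co-clustering frequencies in \[0, 1\].
#' @export
coClusteringFrequency <- function(models, method = "hierarchical",
                                  scaled = TRUE, kValues = 2:4, seed = 1L) {
  n <- nrow(subjectScores(models[[1]]))
  acc <- matrix(0, n, n)
  m <- 0L
  for (model in models) {
    A <- subjectScores(model)
    for (cc in seq_len(ncol(A))) {
      for (k in kValues) {
        lab <- .clusterVector(A[, cc], method, k, scaled, seed = seed)
        acc <- acc + outer(lab, lab, "==")
        m <- m + 1L
      }
    }
  }
  acc / m
}

#' Metabolite stability across the provocation test
#'
#' ICC(2,1) of each metabolite feature over the draw schedule, treating
#' the 8 timepoints as repeated occasions per subject: low ICC means the
#' provocation perturbs that feature's rank order between subjects.
#' Computed on log intensities by default.
#'
#' @param tensor a complete [ProvocationTensor-class].
#' @param log compute on `log` intensities (requires positive values)?
#' @return named numeric vector, one ICC per feature.
#' @export
metaboliteStability <- function(tensor, log = TRUE) {
  vals <- tensorValues(tensor)
  if (anyNA(vals))
    stop("tensor has missing cells; impute first", call. = FALSE)
  if (log) {
    if (any(vals <= 0))
      stop("log stability needs positive intensities; use log = FALSE",
           call. = FALSE)
    vals <- base::log(vals)
  }
  out <- vapply(seq_len(dim(vals)[2]), function(j)
    icc21(vals[, j, ]), numeric(1))
  names(out) <- tensor@featureIds
  out
}
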