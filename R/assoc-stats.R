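#' @include parafac-linkage.R
NULL

#' ICC(2,1): two-way random effects, single measure, absolute agreement
#'
#' Intraclass correlation from the two-way random-effects ANOVA
#' decomposition of a subjects x occasions matrix:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`,
#' where MSR, MSC, MSE are the between-subject, between-occasion and
#' residual mean squares, n the number of subjects and k the number of
#' occasions.
#'
#' @param m numeric matrix, subjects in rows (n >= 2), occasions in
#'   columns (k >= 2), no missing cells.
#' @return the ICC (a single value in (-1, 1\]).
#' @examples
#' m <- cbind(1:4, 1:4, 1:4)
#' icc21(m)  # identical columns: 1
#' @export
icc21 <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L)
    stop("need at least 2 subjects and 2 occasions", call. = FALSE)
  if (anyNA(m)) stop("no missing cells allowed", call. = FALSE)
  grand <- mean(m)
  if (sum((m - grand)^2) == 0)
    stop("zero total variance: ICC undefined", call. = FALSE)
  rowM <- rowMeans(m); colM <- colMeans(m)
  msr <- k * sum((rowM - grand)^2) / (n - 1)
  msc <- n * sum((colM - grand)^2) / (k - 1)
  sse <- sum((m - outer(rowM, rep(1, k)) -
                outer(rep(1, n), colM) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' One-way ANOVA
#'
#' Classical fixed-effects one-way analysis of variance (homoscedastic F
#' test), as used to link cluster labels to continuous variables.
#'
#' @param values numeric vector.
#' @param groups group labels (any type coercible to factor); at least 2
#'   groups with at least 2 observations each.
#' @return list with `F` and `p`.
#' @examples
#' onewayAnova(c(1, 2, 3, 4, 5, 6), rep(1:2, each = 3))  # F = 13.5
#' @export
onewayAnova <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2L)
    stop("need at least two groups", call. = FALSE)
  if (any(table(g) < 2L))
    stop("every group needs at least two observations", call. = FALSE)
  ft <- stats::oneway.test(values ~ g, var.equal = TRUE)
  F <- unname(ft$statistic)
  p <- unname(ft$p.value)
  if (is.nan(F)) { F <- 0; p <- 1 }   # zero within+between variance
  list(F = F, p = p)
}

#' Fisher's exact test
#'
#' Exact test of independence for an r x c contingency table: the classic
#' two-sided hypergeometric test for 2 x 2 tables, exact network
#' enumeration for small r x c tables, and a seeded Monte-Carlo estimate
#' (1e5 draws) for tables too large to enumerate.
#'
#' @param table matrix of non-negative integer counts with positive
#'   margins.
#' @param mcCutoff total count above which (for tables beyond 2 x 2) the
#'   Monte-Carlo path is taken.
#' @param seed RNG seed for the Monte-Carlo path.
#' @return the two-sided p value.
#' @examples
#' fisherExact(matrix(c(3, 1, 1, 3), 2))  # 34/70
#' @export
fisherExact <- function(table, mcCutoff = 200L, seed = 1L) {
  tb <- as.matrix(table)
  if (any(tb < 0) || any(tb != round(tb)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (any(rowSums(tb) == 0) || any(colSums(tb) == 0))
    stop("all margins must be positive", call. = FALSE)
  exact <- all(dim(tb) == 2L) ||
    (sum(tb) <= mcCutoff && prod(dim(tb)) <= 20L)
  res <- if (exact) {
    stats::fisher.test(tb)
  } else {
    withr::with_seed(as.integer(seed),
      stats::fisher.test(tb, simulate.p.value = TRUE, B = 1e5))
  }
  unname(res$p.value)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment with enforced monotonicity; input order is
#' preserved.
#'
#' @param p numeric vector of p values in \[0, 1\].
#' @return adjusted p values, same order as the input.
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhFdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Characterize metabotype clusters against baseline clinical data
#'
#' For an assignment that survived permutation testing, screens every
#' baseline clinical variable for association with the cluster labels:
#' one-way ANOVA for continuous variables, Fisher's exact test for
#' categorical ones, with Benjamini-Hochberg adjustment across variables
#' and significance called at adjusted p < 0.05. Variables with a single
#' observed level are skipped with a warning.
#'
#' @param assignment a [ClusterAssignment-class].
#' @param baseline data.frame of clinical variables, rownames = subject
#'   ids (e.g. [clinicalData()]).
#' @param alpha adjusted-p significance level (default 0.05).
#' @return data.frame: `variable`, `test`, `p`, `p_adj`, `significant`.
#' @export
characterizeClusters <- function(assignment, baseline, alpha = 0.05) {
  lab <- clusterLabels(assignment)
  ids <- intersect(names(lab), rownames(baseline))
  lab <- lab[ids]
  df <- baseline[ids, , drop = FALSE]
  rows <- lapply(names(df), function(v) {
    col <- df[[v]]
    if (is.numeric(col)) {
      ok <- tryCatch({
        ft <- onewayAnova(col, lab)
        data.frame(variable = v, test = "anova", p = ft$p)
      }, error = function(e) NULL)
    } else {
      col <- factor(col)
      ok <- if (nlevels(droplevels(col)) < 2L) NULL else
        data.frame(variable = v, test = "fisher",
                   p = fisherExact(table(droplevels(col), lab)))
    }
    if (is.null(ok))
      warning("variable '", v, "' skipped (single observed level or ",
              "degenerate groups)", call. = FALSE)
    ok
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(variable = character(), test = character(),
                      p = numeric(), p_adj = numeric(),
                      significant = logical()))
  out$p_adj <- bhFdr(out$p)
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}
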