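#' @include parafac-impute.R
NULL

## Khatri-Rao (column-wise Kronecker) product with row index running
## fastest over the FIRST argument: rows are (j, k) pairs with j fastest.
.khatriRao <- function(K, J) {
  ## returns (nrow(J) * nrow(K)) x C with row (j + (k-1)*nJ)
  K[rep(seq_len(nrow(K)), each = nrow(J)), , drop = FALSE] *
    J[rep(seq_len(nrow(J)), nrow(K)), , drop = FALSE]
}

## Mode unfoldings with consistent index conventions:
##  mode 1: n x (p t), column j + (k-1) p
##  mode 2: p x (n t), column i + (k-1) n
##  mode 3: t x (n p), column i + (j-1) n
.unfold <- function(x, mode) {
  d <- dim(x)
  switch(mode,
    matrix(aperm(x, c(1, 2, 3)), d[1], d[2] * d[3]),
    matrix(aperm(x, c(2, 1, 3)), d[2], d[1] * d[3]),
    matrix(aperm(x, c(3, 1, 2)), d[3], d[1] * d[2]))
}

.solveGram <- function(M, G) {
  ## M %*% G^-1 with a pseudo-inverse fallback for rank-deficient Grams
  out <- tryCatch(t(solve(G, t(M))), error = function(e) NULL)
  if (is.null(out)) {
    sv <- svd(G)
    pos <- sv$d > max(sv$d) * 1e-12
    Ginv <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
    out <- M %*% t(Ginv)
  }
  out
}

.svdInit <- function(M, C, seed) {
  k <- min(C, nrow(M) - 0L, ncol(M))
  sv <- svd(M, nu = k, nv = 0)
  out <- sv$u
  if (k < C) {
    extra <- withr::with_seed(seed,
      matrix(stats::rnorm(nrow(M) * (C - k)), nrow(M)))
    out <- cbind(out, extra)
  }
  out
}

#' PARAFAC by alternating least squares
#'
#' Fits the trilinear model `X ~ sum_r a_r (o) b_r (o) d_r` to a complete,
#' preprocessed tensor by alternating least squares over the three mode
#' unfoldings, until the relative change in residual sum of squares falls
#' below `tol`. At exit, feature and time loadings are normalized to unit
#' columns (magnitude carried into the subject scores), the
#' largest-magnitude element of each time (and feature) loading is made
#' positive, and components are ordered by decreasing magnitude. A
#' degeneracy warning is raised when two components' triple cosine falls
#' below -0.85; hitting `maxIter` flags the model as non-converged but
#' does not raise.
#'
#' @param tensor a complete [ProvocationTensor-class].
#' @param nComponents number of components C (2--20 in the screening
#'   protocol); at most `min(n, p*t)`.
#' @param init `svd` (leading singular vectors of each unfolding;
#'   deterministic) or `random` (seeded; used for degeneracy diagnostics).
#' @param tol relative SSE change for convergence (default 1e-8).
#' @param maxIter iteration cap (default 500).
#' @param seed RNG seed (random init, and padding when C exceeds a mode's
#'   rank).
#' @return A [ParafacModel-class].
#' @export
parafacALS <- function(tensor, nComponents, init = c("svd", "random"),
                       tol = 1e-8, maxIter = 500L, seed = 1L) {
  init <- match.arg(init)
  x <- tensorValues(tensor)
  if (anyNA(x))
    stop("tensor has missing cells; impute first", call. = FALSE)
  d <- dim(x)
  C <- as.integer(nComponents)
  if (C < 1L || C > min(d[1], d[2] * d[3]))
    stop("nComponents must lie in 1..min(n, p*t)", call. = FALSE)
  X1 <- .unfold(x, 1); X2 <- .unfold(x, 2); X3 <- .unfold(x, 3)
  ssTot <- sum(x^2)

  if (init == "svd") {
    A <- .svdInit(X1, C, seed)
    B <- .svdInit(X2, C, seed + 1L)
    D <- .svdInit(X3, C, seed + 2L)
  } else {
    fct <- withr::with_seed(as.integer(seed), list(
      A = matrix(stats::rnorm(d[1] * C), d[1]),
      B = matrix(stats::rnorm(d[2] * C), d[2]),
      D = matrix(stats::rnorm(d[3] * C), d[3])))
    A <- fct$A; B <- fct$B; D <- fct$D
  }

  sseTrace <- numeric(0)
  ssePrev <- Inf
  converged <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    A <- .solveGram(X1 %*% .khatriRao(D, B), crossprod(B) * crossprod(D))
    B <- .solveGram(X2 %*% .khatriRao(D, A), crossprod(A) * crossprod(D))
    D <- .solveGram(X3 %*% .khatriRao(B, A), crossprod(A) * crossprod(B))
    rec1 <- A %*% t(.khatriRao(D, B))
    sse <- sum((X1 - rec1)^2)
    sseTrace <- c(sseTrace, sse)
    ## relative to the total SS so the criterion stays meaningful as the
    ## residual approaches zero on noise-free tensors
    if (sse <= 1e-14 * ssTot ||
        (is.finite(ssePrev) && abs(ssePrev - sse) <= tol * ssTot)) {
      converged <- TRUE
      break
    }
    ssePrev <- sse
  }

  ## normalization, sign and ordering conventions
  for (r in seq_len(C)) {
    nb <- sqrt(sum(B[, r]^2)); nd <- sqrt(sum(D[, r]^2))
    if (nb > 0) { B[, r] <- B[, r] / nb } ; if (nd > 0) D[, r] <- D[, r] / nd
    A[, r] <- A[, r] * nb * nd
    if (D[which.max(abs(D[, r])), r] < 0) {
      D[, r] <- -D[, r]; A[, r] <- -A[, r]
    }
    if (B[which.max(abs(B[, r])), r] < 0) {
      B[, r] <- -B[, r]; A[, r] <- -A[, r]
    }
  }
  ord <- order(colSums(A^2), decreasing = TRUE)
  A <- A[, ord, drop = FALSE]
  B <- B[, ord, drop = FALSE]
  D <- D[, ord, drop = FALSE]

  if (C > 1L) {
    cosm <- function(M) {
      cn <- sqrt(colSums(M^2)); crossprod(M) / outer(cn, cn)
    }
    triple <- cosm(A) * cosm(B) * cosm(D)
    if (any(triple[upper.tri(triple)] < -0.85))
      warning("degenerate component pair (triple cosine < -0.85)",
              call. = FALSE)
  }

  methods::new("ParafacModel",
    A = A, B = B, D = D,
    fit = 1 - sseTrace[length(sseTrace)] / ssTot,
    iterations = it, converged = converged, sseTrace = sseTrace)
}

#' Tucker congruence of a fitted model against reference factors
#'
#' Scores component recovery up to permutation and sign: the fitted
#' components are matched to the reference components by the permutation
#' maximizing total congruence (exhaustive for up to 6 components, greedy
#' beyond), and the absolute cosine between matched columns is reported
#' per mode.
#'
#' @param model a [ParafacModel-class].
#' @param refA,refB,refD reference factor matrices (e.g. a generator's
#'   ground truth), same row dimensions as the model's.
#' @return matrix `3 x C` of congruences (rows: subject, feature, time
#'   modes), with the matching permutation in attribute `perm`.
#' @export
tuckerCongruence <- function(model, refA, refB, refD) {
  congr <- function(M, R) {
    cm <- sqrt(colSums(M^2)); cr <- sqrt(colSums(R^2))
    abs(crossprod(M, R)) / outer(cm, cr)
  }
  cA <- congr(subjectScores(model), as.matrix(refA))
  cB <- congr(featureLoadings(model), as.matrix(refB))
  cD <- congr(timeLoadings(model), as.matrix(refD))
  C <- ncol(cA)
  total <- cA * cB * cD
  perm <- if (C <= 6L) {
    perms <- .allPerms(C)
    scores <- vapply(perms, function(p)
      sum(total[cbind(seq_len(C), p)]), numeric(1))
    perms[[which.max(scores)]]
  } else {
    p <- integer(C); used <- logical(C)
    for (r in order(apply(total, 1, max), decreasing = TRUE)) {
      j <- which.max(ifelse(used, -Inf, total[r, ]))
      p[r] <- j; used[j] <- TRUE
    }
    p
  }
  out <- rbind(
    subject = cA[cbind(seq_len(C), perm)],
    feature = cB[cbind(seq_len(C), perm)],
    time    = cD[cbind(seq_len(C), perm)])
  attr(out, "perm") <- perm
  out
}

.allPerms <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    for (p in .allPerms(k - 1L))
      out[[length(out) + 1L]] <- c(i, rest[p])
  }
  out
}
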