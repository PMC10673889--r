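#' Cosine ground cost between features
#'
#' Builds the feature-by-feature ground cost used by the optimal-transport
#' reconstruction loss: \eqn{C_{k,l} = 1 - \langle u_k, u_l\rangle /
#' (\|u_k\|\,\|u_l\|)} where \eqn{u_k} is the expression profile of
#' feature \eqn{k} across cells. For nonnegative data the entries lie in
#' \[0, 1\]; the matrix is symmetric with zero diagonal.
#'
#' Features with zero norm cannot be placed in the cosine geometry; by
#' default they are dropped with a warning (the usual situation after
#' variable-feature selection is that none remain), or an error can be
#' requested.
#'
#' @param featureMatrix Features-by-cells matrix (dense or sparse).
#' @param onZeroNorm `"drop"` (default) or `"error"`.
#' @return A list with `cost` (the matrix, with feature dimnames) and
#'   `kept` (indices of retained features).
#' @export
cosineCost <- function(featureMatrix, onZeroNorm = c("drop", "error")) {
  onZeroNorm <- match.arg(onZeroNorm)
  m <- as.matrix(featureMatrix)
  nrm <- sqrt(rowSums(m^2))
  zero <- which(nrm == 0)
  if (length(zero)) {
    ids <- rownames(m)[zero]
    if (is.null(ids)) ids <- as.character(zero)
    if (onZeroNorm == "error")
      stop("zero-norm feature(s): ", paste(utils::head(ids, 5),
                                           collapse = ", "))
    warning("dropping ", length(zero), " zero-norm feature(s) before ",
            "cost construction")
    m <- m[-zero, , drop = FALSE]
    nrm <- nrm[-zero]
  }
  u <- m / nrm
  C <- 1 - tcrossprod(u)
  C[C < 0] <- 0
  C <- (C + t(C)) / 2
  diag(C) <- 0
  kept <- setdiff(seq_len(nrow(featureMatrix)), zero)
  list(cost = C, kept = kept)
}

#' Optimal-transport context
#'
#' Bundles a validated ground cost with the entropic regularization
#' \eqn{\varepsilon}. Costs are precomputed once per modality; a memory
#' guard refuses feature counts whose squared size would exceed
#' `maxCostEntries`, pointing at feature selection instead.
#'
#' @param cost Square symmetric nonnegative matrix with zero diagonal
#'   (entries in \[0, 2\]).
#' @param eps Positive entropic regularization (default 0.05, a compromise
#'   between closeness to unregularized transport and Sinkhorn speed on
#'   cosine costs in \[0, 1\]).
#' @param modality Label for reporting.
#' @param maxCostEntries Memory guard on `length(cost)`.
#' @return An [OTContext-class].
#' @export
otContext <- function(cost, eps = 0.05, modality = "view",
                      maxCostEntries = 2.5e7) {
  if (length(cost) > maxCostEntries)
    stop("ground cost for '", modality, "' has ", length(cost),
         " entries, above the memory budget; reduce the number of ",
         "selected features")
  methods::new("OTContext", cost = as.matrix(cost), eps = eps,
               modality = modality)
}

#' Shannon entropy of a nonnegative array
#'
#' \eqn{E(X) = -\sum_{i} X_i \log X_i} with the convention
#' \eqn{0 \log 0 = 0}.
#'
#' @param x Nonnegative vector or matrix.
#' @return The entropy (a single number).
#' @export
shannonEntropy <- function(x) {
  v <- as.numeric(x)
  v <- v[v > 0]
  -sum(v * log(v))
}

#' Column-wise softmax
#'
#' Maps each column \eqn{c} to \eqn{\exp(c) / \sum \exp(c)}, computed with
#' a per-column max shift so it is exact under additive shifts and safe for
#' large magnitudes. Output columns are on the probability simplex.
#'
#' @param x Numeric matrix.
#' @return Matrix of the same shape with columns summing to 1.
#' @export
softmaxCols <- function(x) {
  x <- as.matrix(x)
  x <- sweep(x, 2, apply(x, 2, max))
  e <- exp(x)
  sweep(e, 2, colSums(e), "/")
}

#' Column-wise log-sum-exp (the negentropy conjugate)
#'
#' The Legendre conjugate of the negative entropy restricted to the
#' simplex, applied column by column and summed:
#' \eqn{\sum_j \log \sum_i \exp(Y_{ij})}, evaluated with max-shift
#' stabilization.
#'
#' @param y Numeric matrix (or vector, treated as one column).
#' @return A single number.
#' @export
negentropyConjugate <- function(y) {
  y <- as.matrix(y)
  mx <- apply(y, 2, max)
  fin <- is.finite(mx)
  s <- numeric(ncol(y))
  s[fin] <- mx[fin] +
    log(colSums(exp(sweep(y[, fin, drop = FALSE], 2, mx[fin]))))
  s[!fin] <- mx[!fin]
  sum(s)
}

#' Entropy-regularized optimal transport between two histograms
#'
#' Solves \eqn{OT_\varepsilon(a, b) = \min_{P \in \Pi(a,b)}
#' \sum P_{k,l} C_{k,l} - \varepsilon E(P)} by log-domain Sinkhorn
#' iterations. Zero-mass bins receive \eqn{-\infty} potentials and zero
#' plan rows without producing NaN.
#'
#' @param a,b Histograms (nonnegative, summing to 1) over the rows/columns
#'   of the context's cost.
#' @param ctx An [OTContext-class].
#' @param tol Termination tolerance on the maximal marginal violation of
#'   the plan (default 1e-6).
#' @param maxIter Iteration cap; non-convergence warns with the achieved
#'   violation rather than failing silently.
#' @return List with `plan` (the coupling), `value`
#'   (\eqn{\sum PC - \varepsilon E(P)} at the returned plan),
#'   `marginalError` and `iterations`.
#' @export
sinkhorn <- function(a, b, ctx, tol = 1e-6, maxIter = 2000) {
  stopifnot(tol > 0)
  .checkHistogram(a, nrow(ctx@cost))
  .checkHistogram(b, nrow(ctx@cost))
  r <- .sinkhornBatchCpp(cbind(a), cbind(b), ctx@cost, ctx@eps, tol,
                         as.integer(maxIter))
  if (r$violation[1] > tol)
    warning(sprintf(
      "Sinkhorn did not reach tol %.1e in %d iterations (violation %.2e)",
      tol, maxIter, r$violation[1]))
  f <- r$f[, 1]
  g <- r$g[, 1]
  P <- exp((outer(f, g, "+") - ctx@cost) / ctx@eps)
  P[!is.finite(P)] <- 0
  list(plan = P, value = sum(P * ctx@cost) - ctx@eps * shannonEntropy(P),
       marginalError = r$violation[1], iterations = r$iterations[1])
}

.checkHistogram <- function(a, m) {
  if (length(a) != m) stop("histogram length does not match the cost")
  if (any(a < 0)) stop("histogram entries must be nonnegative")
  if (abs(sum(a) - 1) > 1e-6) stop("histogram must sum to 1")
  invisible(TRUE)
}

#' Legendre conjugate of the entropic OT loss
#'
#' Closed-form evaluation of \eqn{OT^\star_\varepsilon(g, a)}, the
#' conjugate of \eqn{x \mapsto OT_\varepsilon(x, a)}:
#' \deqn{OT^\star_\varepsilon(g, a) = \varepsilon \sum_l a_l\,
#'   \mathrm{LSE}_k\!\left((g_k - C_{k,l})/\varepsilon\right)
#'   + \varepsilon E(a),}
#' evaluated in the log domain. This is the smooth building block of the
#' dual subproblems solved during fitting.
#'
#' @param g Dual vector (length = number of bins).
#' @param a Histogram on the simplex.
#' @param ctx An [OTContext-class].
#' @return The conjugate value (a single number).
#' @export
otDualValue <- function(g, a, ctx) {
  .checkHistogram(a, nrow(ctx@cost))
  .otConjBatchCpp(cbind(g), cbind(a), ctx@cost, ctx@eps, FALSE)$value
}

#' Gradient of the entropic OT conjugate
#'
#' \eqn{\nabla_g OT^\star_\varepsilon(g, a)} is the source marginal of the
#' optimal plan transporting towards `a`: entries are nonnegative and sum
#' to 1 (it is itself a histogram).
#'
#' @inheritParams otDualValue
#' @return Numeric vector of the same length as `g`.
#' @export
otDualGrad <- function(g, a, ctx) {
  .checkHistogram(a, nrow(ctx@cost))
  as.numeric(.otConjBatchCpp(cbind(g), cbind(a), ctx@cost, ctx@eps,
                             TRUE)$grad)
}

# Batched conjugate over all cells: G, A are m x n; returns value summed
# over columns and (optionally) the m x n gradient.
.otConjBatch <- function(G, A, cost, eps, wantGrad = TRUE) {
  .otConjBatchCpp(G, A, cost, eps, wantGrad)
}

# Batched Sinkhorn values OT_eps(x_j, a_j) over columns.
.sinkhornValues <- function(X, A, cost, eps, tol = 1e-6, maxIter = 2000) {
  r <- .sinkhornBatchCpp(X, A, cost, eps, tol, as.integer(maxIter))
  if (max(r$violation) > tol)
    warning(sprintf(
      "batched Sinkhorn: %d column(s) above tol (worst violation %.2e)",
      sum(r$violation > tol), max(r$violation)))
  r$values
}
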