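# Independent reference implementations used as oracles. These are written
# in plain R, directly from the defining formulas, and never call the
# package's optimized code paths.

refLSE <- function(v) {
  mx <- max(v)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(v - mx)))
}

refEntropy <- function(x) {
  v <- as.numeric(x)
  v <- v[v > 0]
  -sum(v * log(v))
}

# Conjugate of the entropic OT loss, straight from its closed form.
refOTConj <- function(g, a, C, eps) {
  m <- length(g)
  L <- vapply(seq_len(m), function(l) refLSE((g - C[, l]) / eps),
              numeric(1))
  eps * sum(a * L) + eps * refEntropy(a)
}

# Plain (slow, dense) log-domain Sinkhorn for small problems.
refSinkhorn <- function(a, b, C, eps, tol = 1e-10, maxit = 20000) {
  m <- length(a)
  f <- numeric(m)
  g <- numeric(m)
  la <- log(a)
  lb <- log(b)
  P <- NULL
  for (it in seq_len(maxit)) {
    for (k in seq_len(m)) f[k] <- eps * (la[k] - refLSE((g - C[k, ]) / eps))
    for (l in seq_len(m)) g[l] <- eps * (lb[l] - refLSE((f - C[, l]) / eps))
    P <- exp((outer(f, g, "+") - C) / eps)
    P[!is.finite(P)] <- 0
    if (max(abs(rowSums(P) - a), abs(colSums(P) - b)) < tol) break
  }
  list(plan = P, value = sum(P * C) - eps * refEntropy(P))
}

# Exact OT cost by linear programming (boot::simplex), small m only.
refExactOT <- function(a, b, C) {
  m <- length(a)
  A3 <- matrix(0, 2 * m, m * m)
  for (k in seq_len(m)) for (l in seq_len(m)) {
    j <- (l - 1) * m + k
    A3[k, j] <- 1
    A3[m + l, j] <- 1
  }
  # drop the last (redundant) equality constraint
  s <- boot::simplex(a = as.vector(C), A3 = A3[-(2 * m), ],
                     b3 = c(a, b)[-(2 * m)], maxi = FALSE)
  s$value
}

# Random simplex matrix (columns sum to 1).
randSimplexMat <- function(m, n) {
  x <- matrix(stats::rexp(m * n), m, n)
  sweep(x, 2, colSums(x), "/")
}

# Random symmetric cost with zero diagonal in [0, 1].
randCost <- function(m) {
  C <- matrix(stats::runif(m * m), m, m)
  C <- (C + t(C)) / 2
  diag(C) <- 0
  C
}

# Tiny two-view simplex dataset for optimizer tests.
tinyDataset <- function(m = 3, n = 4, d = 2, seed = 1) {
  set.seed(seed)
  views <- lapply(seq_len(d), function(p) {
    A <- randSimplexMat(m, n)
    dimnames(A) <- list(sprintf("v%d_f%d", p, seq_len(m)),
                        sprintf("c%d", seq_len(n)))
    OmicsView(paste0("view", p), A, isSimplex = TRUE)
  })
  names(views) <- paste0("view", seq_len(d))
  MultiOmicsDataset(views)
}

# Full primal loss computed entirely with reference routines.
refTotalLoss <- function(Hs, W, As, Cs, eps, rho, mu) {
  loss <- 0
  for (p in seq_along(As)) {
    X <- Hs[[p]] %*% W
    for (j in seq_len(ncol(W)))
      loss <- loss + refSinkhorn(X[, j], As[[p]][, j], Cs[[p]], eps)$value
    loss <- loss - rho[p] * refEntropy(Hs[[p]]) - mu * refEntropy(W)
  }
  loss
}
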