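test_that("cosine cost matches the defining formula", {
  u <- rbind(a = c(1, 0), b = c(0, 1), c = c(1, 1))
  C <- cosineCost(u)$cost
  expect_equal(C["a", "a"], 0)
  expect_equal(C["a", "b"], 1)
  expect_equal(C["a", "c"], 1 - 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(C, t(C))
  expect_equal(unname(diag(C)), c(0, 0, 0))

  u0 <- rbind(a = c(1, 1), z = c(0, 0))
  expect_warning(cc <- cosineCost(u0), "zero-norm")
  expect_equal(cc$kept, 1L)
  expect_error(cosineCost(u0, onZeroNorm = "error"), "zero-norm")
})

test_that("entropy follows -sum x log x with 0 log 0 = 0", {
  expect_equal(shannonEntropy(c(0, 1, 0)), 0)
  expect_equal(shannonEntropy(rep(1 / 5, 5)), log(5))
  expect_equal(shannonEntropy(c(0.5, 0.5)), log(2), tolerance = 1e-12)
})

test_that("softmax columns are simplex and shift-invariant", {
  expect_equal(unname(softmaxCols(cbind(c(0, 0)))), cbind(c(0.5, 0.5)))
  expect_equal(unname(softmaxCols(cbind(log(c(1, 3))))),
               cbind(c(0.25, 0.75)), tolerance = 1e-12)
  set.seed(3)
  X <- matrix(rnorm(20), 4, 5)
  expect_equal(softmaxCols(X), softmaxCols(sweep(X, 2, rnorm(5), "+")),
               tolerance = 1e-12)
  expect_equal(unname(colSums(softmaxCols(X))), rep(1, 5))
})

test_that("negentropy conjugate is a stabilized column LSE sum", {
  expect_equal(negentropyConjugate(cbind(c(0, 0))), log(2))
  expect_equal(negentropyConjugate(cbind(c(5, -Inf, -Inf))), 5)
  set.seed(4)
  Y <- matrix(rnorm(6), 3, 2)
  naive <- sum(log(colSums(exp(Y))))
  expect_equal(negentropyConjugate(Y), naive, tolerance = 1e-12)
  # no overflow on large magnitudes
  expect_true(is.finite(negentropyConjugate(Y + 1000)))
})

test_that("sinkhorn satisfies its marginal and value contracts", {
  set.seed(10)
  m <- 4
  C <- randCost(m)
  a <- randSimplexMat(m, 1)[, 1]
  b <- randSimplexMat(m, 1)[, 1]
  ctx <- otContext(C, eps = 0.05)
  s <- sinkhorn(a, b, ctx)
  expect_lt(s$marginalError, 1e-6)
  expect_lt(max(abs(rowSums(s$plan) - a)), 2e-6)
  expect_lt(max(abs(colSums(s$plan) - b)), 2e-6)
  expect_equal(s$value, sum(s$plan * C) - 0.05 * shannonEntropy(s$plan),
               tolerance = 1e-8)

  # value agrees with the independent dense reference
  ref <- refSinkhorn(a, b, C, 0.05)
  expect_equal(s$value, ref$value, tolerance = 1e-5)

  # symmetry in its arguments (symmetric cost)
  s2 <- sinkhorn(b, a, ctx)
  expect_equal(s$value, s2$value, tolerance = 1e-6)
})

test_that("sinkhorn limits: identity transport and outer-product plan", {
  m <- 3
  C <- randCost(m)
  a <- c(0.2, 0.5, 0.3)
  sId <- sinkhorn(a, a, otContext(C, eps = 1e-3), maxIter = 20000)
  expect_lt(abs(sId$value), 5e-3)  # near-zero self-transport cost

  # analytic limit: the plan deviates from a b^T by order C/eps per entry
  b <- c(0.6, 0.1, 0.3)
  sBig <- sinkhorn(a, b, otContext(C, eps = 1e5))
  expect_lt(max(abs(sBig$plan - outer(a, b))), 1e-6)
})

test_that("sinkhorn transport cost approaches the exact LP optimum", {
  skip_if_not_installed("boot")
  set.seed(11)
  for (m in 3:5) {
    C <- randCost(m)
    a <- randSimplexMat(m, 1)[, 1]
    b <- randSimplexMat(m, 1)[, 1]
    s <- sinkhorn(a, b, otContext(C, eps = 1e-3), maxIter = 50000)
    lp <- refExactOT(a, b, C)
    expect_lt(abs(sum(s$plan * C) - lp), 1e-2)
  }
})

test_that("zero-mass bins produce finite log-domain results", {
  C <- randCost(4)
  a <- c(0.5, 0.5, 0, 0)
  b <- c(0, 0.25, 0.25, 0.5)
  s <- sinkhorn(a, b, otContext(C, eps = 0.05))
  expect_true(all(is.finite(s$plan)))
  expect_true(is.finite(s$value))
  expect_lt(max(abs(rowSums(s$plan) - a)), 2e-6)
})

test_that("transport cost part is non-decreasing in eps", {
  set.seed(12)
  m <- 4
  C <- randCost(m)
  a <- randSimplexMat(m, 1)[, 1]
  b <- randSimplexMat(m, 1)[, 1]
  costs <- vapply(c(1e-3, 1e-2, 0.1, 1), function(e) {
    s <- sinkhorn(a, b, otContext(C, eps = e), maxIter = 50000)
    sum(s$plan * C)
  }, numeric(1))
  expect_true(all(diff(costs) >= -1e-9))
})

test_that("OT conjugate matches hand evaluation and reference", {
  # m = 2, g = 0: direct scalar arithmetic
  c12 <- 0.4
  C <- matrix(c(0, c12, c12, 0), 2, 2)
  a <- c(0.3, 0.7)
  eps <- 0.05
  byHand <- eps * (a[1] * log(exp(0) + exp(-c12 / eps)) +
                   a[2] * log(exp(-c12 / eps) + exp(0))) +
    eps * (-a[1] * log(a[1]) - a[2] * log(a[2]))
  ctx <- otContext(C, eps = eps)
  expect_equal(otDualValue(c(0, 0), a, ctx), byHand, tolerance = 1e-12)

  set.seed(13)
  for (rep in 1:5) {
    m <- 5
    C <- randCost(m)
    a <- randSimplexMat(m, 1)[, 1]
    g <- rnorm(m, 0, 0.3)
    ctx <- otContext(C, eps = 0.05)
    expect_equal(otDualValue(g, a, ctx), refOTConj(g, a, C, 0.05),
                 tolerance = 1e-10)
  }
})

test_that("OT conjugate gradient matches finite differences, sums to 1", {
  set.seed(14)
  m <- 5
  C <- randCost(m)
  a <- randSimplexMat(m, 1)[, 1]
  g <- rnorm(m, 0, 0.3)
  ctx <- otContext(C, eps = 0.05)
  gr <- otDualGrad(g, a, ctx)
  expect_equal(sum(gr), 1, tolerance = 1e-10)
  expect_true(all(gr >= 0))
  h <- 1e-6
  fd <- vapply(seq_len(m), function(i) {
    e <- numeric(m); e[i] <- h
    (otDualValue(g + e, a, ctx) - otDualValue(g - e, a, ctx)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(fd - gr)), 1e-5)
})

test_that("Fenchel-Young holds with equality at the conjugate gradient", {
  set.seed(15)
  m <- 4
  C <- randCost(m)
  a <- randSimplexMat(m, 1)[, 1]
  g <- rnorm(m, 0, 0.2)
  ctx <- otContext(C, eps = 0.1)
  conj <- otDualValue(g, a, ctx)
  # equality at x = grad
  x <- otDualGrad(g, a, ctx)
  gap0 <- refSinkhorn(x, a, C, 0.1)$value + conj - sum(g * x)
  expect_lt(abs(gap0), 1e-6)
  # inequality at random x
  for (rep in 1:3) {
    xr <- randSimplexMat(m, 1)[, 1]
    gap <- refSinkhorn(xr, a, C, 0.1)$value + conj - sum(g * xr)
    expect_gte(gap, -1e-8)
  }
})

test_that("OT conjugate is convex in g (midpoint inequality)", {
  set.seed(16)
  m <- 4
  C <- randCost(m)
  a <- randSimplexMat(m, 1)[, 1]
  ctx <- otContext(C, eps = 0.05)
  for (rep in 1:5) {
    g1 <- rnorm(m, 0, 0.5)
    g2 <- rnorm(m, 0, 0.5)
    mid <- otDualValue((g1 + g2) / 2, a, ctx)
    expect_lte(mid, (otDualValue(g1, a, ctx) +
                       otDualValue(g2, a, ctx)) / 2 + 1e-10)
  }
})

test_that("large eps turns the conjugate gradient into a softmax", {
  # eps -> Inf: LSE_k((g_k - C_kl)/eps) -> softmax weights independent of a
  C <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  a <- c(0.4, 0.6)
  g <- c(0.3, -0.2)
  eps <- 1000
  ctx <- otContext(C, eps = eps)
  gr <- otDualGrad(g, a, ctx)
  # direct m = 2 formula: row k gets sum_l a_l softmax_k((g - C[,l])/eps)
  direct <- vapply(1:2, function(k) {
    sum(vapply(1:2, function(l) {
      w <- exp((g - C[, l]) / eps)
      a[l] * w[k] / sum(w)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(gr, direct, tolerance = 1e-10)
})

test_that("cost validation rejects malformed contexts", {
  C <- randCost(3)
  Cb <- C; Cb[1, 2] <- Cb[1, 2] + 1e-3  # asymmetric
  expect_error(otContext(Cb, 0.05), "symmetric")
  Cd <- C; diag(Cd) <- 0.1
  expect_error(otContext(Cd, 0.05), "diagonal")
  expect_error(otContext(C, -1), "eps")
  expect_error(otContext(matrix(0, 6000, 6000), 0.05,
                         maxCostEntries = 1e6), "budget")
})
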