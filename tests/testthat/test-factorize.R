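test_that("regularization scaling follows the log-dimension formula", {
  ds <- tinyDataset(m = 3, n = 4, d = 1, seed = 1)
  cfg <- modelConfig(k = 5)
  # rho = rhoTilde / (log(m) k), mu = muTilde / (log(k) n), natural logs
  sc <- scaleRegularization(cfg, ds)
  expect_equal(unname(sc$rho[1]), 0.01 / (log(3) * 5), tolerance = 1e-12)
  expect_equal(sc$mu, 0.001 / (log(5) * 4), tolerance = 1e-12)

  # printed-precision spot checks at the reference dimensions
  expect_equal(0.01 / (log(100) * 5), 4.3429e-4, tolerance = 1e-4)
  expect_equal(0.001 / (log(50) * 1000), 2.556e-7, tolerance = 1e-3)

  # doubling k halves rho exactly
  sc2 <- scaleRegularization(modelConfig(k = 10), ds)
  expect_equal(unname(sc2$rho[1]), unname(sc$rho[1]) / 2, tolerance = 1e-14)

  expect_error(modelConfig(k = 1))
})

test_that("block updates keep columns on the simplex and lower the loss", {
  set.seed(21)
  m <- 3; n <- 4; k <- 2; eps <- 0.1
  ds <- tinyDataset(m = m, n = n, d = 2, seed = 21)
  As <- lapply(viewNames(ds), function(nm) as.matrix(getView(ds, nm)@matrix))
  Cs <- lapply(As, function(A) cosineCost(A)$cost)
  ctxs <- lapply(Cs, otContext, eps = eps)
  sc <- scaleRegularization(modelConfig(k = k, eps = eps), ds)
  rho <- unname(sc$rho); mu <- sc$mu

  W0 <- softmaxCols(matrix(rnorm(k * n, 0, 0.1), k, n))
  H0s <- lapply(As, function(A)
    softmaxCols(matrix(rnorm(nrow(A) * k, 0, 0.1), nrow(A), k)))
  # the primal objective counts the W entropy once per modality
  lossFor <- function(Hs, W)
    refTotalLoss(Hs, W, As, Cs, eps, rho, mu)

  l0 <- lossFor(H0s, W0)
  u1 <- updateH(As[[1]], W0, ctxs[[1]], rho[1])
  expect_equal(unname(colSums(u1$H)), rep(1, k), tolerance = 1e-12)
  l1 <- lossFor(list(u1$H, H0s[[2]]), W0)
  expect_lte(l1, l0 + 1e-6 * abs(l0))

  u2 <- updateH(As[[2]], W0, ctxs[[2]], rho[2])
  l2 <- lossFor(list(u1$H, u2$H), W0)
  expect_lte(l2, l1 + 1e-6 * abs(l1))

  uw <- updateW(As, list(u1$H, u2$H), ctxs, mu)
  expect_equal(unname(colSums(uw$W)), rep(1, n), tolerance = 1e-12)
  l3 <- lossFor(list(u1$H, u2$H), uw$W)
  expect_lte(l3, l2 + 1e-6 * abs(l2))
})

test_that("large rho drives dictionaries to the uniform distribution", {
  ds <- tinyDataset(m = 4, n = 3, d = 1, seed = 22)
  A <- as.matrix(getView(ds, "view1")@matrix)
  ctx <- otContext(cosineCost(A)$cost, eps = 0.1)
  W <- softmaxCols(matrix(rnorm(2 * 3, 0, 0.3), 2, 3))
  u <- updateH(A, W, ctx, rho = 1e6)
  expect_lt(max(abs(u$H - 1 / 4)), 1e-4)
})

test_that("smaller muTilde yields sparser embeddings", {
  ds <- simulateMultiOmics(nCells = c(6, 6, 6),
                           nFeatures = c(rna = 15, atac = 15), seed = 23)
  dsp <- preprocessDataset(ds, nTopRNA = 12, nTopATAC = 12)
  ents <- vapply(c(1e-1, 1e-2, 1e-3), function(mt) {
    fit <- fitFactorModel(dsp, modelConfig(k = 3, muTilde = mt, seed = 5,
                                           outerMaxIter = 6))
    W <- embedding(fit)
    mean(apply(W, 2, shannonEntropy))
  }, numeric(1))
  expect_true(all(diff(ents) <= 1e-8))  # decreasing with muTilde
})

test_that("total loss equals the componentwise reference on a tiny case", {
  set.seed(24)
  m <- 3; n <- 2; k <- 2; eps <- 0.1
  ds <- tinyDataset(m = m, n = n, d = 1, seed = 24)
  A <- as.matrix(getView(ds, "view1")@matrix)
  C <- cosineCost(A)$cost
  H <- randSimplexMat(m, k)
  W <- randSimplexMat(k, n)
  cfg <- modelConfig(k = k, eps = eps)
  sc <- scaleRegularization(cfg, ds)
  model <- methods::new("FactorModel", dictionaries = list(view1 = H),
                        embedding = W, k = as.integer(k),
                        config = unclass(cfg), lossTrace = numeric(0),
                        simplex = TRUE)
  got <- totalLoss(model, ds, tol = 1e-9)
  want <- refTotalLoss(list(H), W, list(A), list(C), eps,
                       unname(sc$rho), sc$mu)
  expect_equal(got, want, tolerance = 1e-7)

  # uniform embedding contributes -mu * n * log(k) of entropy per view
  Wu <- matrix(1 / k, k, n)
  modelU <- methods::new("FactorModel", dictionaries = list(view1 = H),
                         embedding = Wu, k = as.integer(k),
                         config = unclass(cfg), lossTrace = numeric(0),
                         simplex = TRUE)
  lossU <- totalLoss(modelU, ds, tol = 1e-9)
  sinkPart <- sum(vapply(seq_len(n), function(j)
    refSinkhorn((H %*% Wu)[, j], A[, j], C, eps, tol = 1e-9)$value,
    numeric(1)))
  expect_equal(lossU - sinkPart + unname(sc$rho[1]) * refEntropy(H),
               -sc$mu * n * log(k), tolerance = 1e-6)

  Wbad <- W; Wbad[1, 1] <- Wbad[1, 1] + 1e-3
  modelB <- methods::new("FactorModel", dictionaries = list(view1 = H),
                         embedding = W, k = as.integer(k),
                         config = unclass(cfg), lossTrace = numeric(0),
                         simplex = TRUE)
  modelB@embedding <- Wbad
  expect_error(totalLoss(modelB, ds), "simplex")
})

test_that("fitting is deterministic and the loss trace is non-increasing", {
  ds <- simulateMultiOmics(nCells = c(6, 6, 6),
                           nFeatures = c(rna = 15, atac = 15), seed = 25)
  dsp <- preprocessDataset(ds, nTopRNA = 12, nTopATAC = 12)
  cfg <- modelConfig(k = 3, seed = 7, outerMaxIter = 8)
  f1 <- fitFactorModel(dsp, cfg)
  f2 <- fitFactorModel(dsp, cfg)
  expect_lt(max(abs(embedding(f1) - embedding(f2))), 1e-10)
  tr <- lossTrace(f1)
  expect_true(all(diff(tr) <= 1e-6 * pmax(abs(tr[-length(tr)]), 1e-12)))
  expect_s4_class(f1, "FactorModel")
  expect_true(methods::validObject(f1))
})

test_that("fitted loss matches a dense simplex search on a micro problem", {
  # brute force: random search + Nelder-Mead refinement over (H, W)
  set.seed(26)
  m <- 3; n <- 2; k <- 2; eps <- 0.1
  ds <- tinyDataset(m = m, n = n, d = 1, seed = 26)
  A <- as.matrix(getView(ds, "view1")@matrix)
  C <- cosineCost(A)$cost
  cfg <- modelConfig(k = k, eps = eps, seed = 3, outerMaxIter = 60,
                     lossRTol = 1e-9)
  sc <- scaleRegularization(cfg, ds)
  obj <- function(par) {
    H <- softmaxCols(matrix(par[1:(m * k)], m, k))
    W <- softmaxCols(matrix(par[-(1:(m * k))], k, n))
    refTotalLoss(list(H), W, list(A), list(C), eps, unname(sc$rho), sc$mu)
  }
  best <- Inf; bestPar <- NULL
  for (r in 1:300) {
    par <- rnorm(m * k + k * n, 0, 2)
    v <- obj(par)
    if (v < best) { best <- v; bestPar <- par }
  }
  ref <- stats::optim(bestPar, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  fit <- fitFactorModel(ds, cfg)
  fitted <- refTotalLoss(list(fit@dictionaries[[1]]), embedding(fit),
                         list(A), list(C), eps, unname(sc$rho), sc$mu)
  expect_lte(fitted, ref$value + 0.01 * abs(ref$value))
})

test_that("permuting cells permutes the embedding and keeps dictionaries", {
  ds <- simulateMultiOmics(nCells = c(4, 4, 4),
                           nFeatures = c(rna = 10, atac = 10), seed = 27)
  dsp <- preprocessDataset(ds, nTopRNA = 8, nTopATAC = 8)
  set.seed(1)
  perm <- sample(nCells(dsp))
  dsPerm <- otOmics:::.subsetCells(dsp, perm)
  # equivariance holds exactly for the algorithm map; after a finite
  # optimization budget the two trajectories agree to solver tolerance
  cfg <- modelConfig(k = 3, seed = 9, outerMaxIter = 8, innerFactr = 100,
                     innerTol = 1e-9, innerMaxIter = 10000)
  f1 <- suppressWarnings(fitFactorModel(dsp, cfg))
  f2 <- suppressWarnings(fitFactorModel(dsPerm, cfg))
  expect_lt(max(abs(embedding(f1)[, perm] - embedding(f2))), 1e-4)
  for (nm in names(dictionaries(f1)))
    expect_lt(max(abs(dictionaries(f1)[[nm]] - dictionaries(f2)[[nm]])),
              1e-4)
})
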