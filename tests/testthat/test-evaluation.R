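test_that("ARI matches the closed form on a hand-computed table", {
  # contingency [[2,0],[0,2],[1,1]] on 6 items:
  # sum_ij C(nij,2) = 2, sum_i C(ai,2) = 3, sum_j C(bj,2) = 6, C(6,2) = 15
  # ARI = (2 - 3*6/15) / ((3+6)/2 - 3*6/15) = 0.8 / 3.3
  truth <- c(1, 1, 2, 2, 3, 3)
  pred <- c(1, 1, 2, 2, 1, 2)
  expect_equal(ariScore(truth, pred), 0.8 / 3.3, tolerance = 1e-12)

  expect_equal(ariScore(truth, truth), 1)
  expect_equal(ariScore(truth, rep(1, 6)), 0)
  expect_error(ariScore(1:3, 1:4), "length")
})

test_that("ARI agrees with an independent implementation and is
           permutation invariant", {
  skip_if_not_installed("mclust")
  set.seed(51)
  for (rep in 1:10) {
    t <- sample(3, 40, replace = TRUE)
    p <- sample(4, 40, replace = TRUE)
    expect_equal(ariScore(t, p), mclust::adjustedRandIndex(t, p),
                 tolerance = 1e-12)
    # invariance under relabeling of either argument
    expect_equal(ariScore(t, p), ariScore(c("x", "y", "z")[t], p),
                 tolerance = 1e-12)
    expect_equal(ariScore(t, p), ariScore(t, 5 - p), tolerance = 1e-12)
  }
})

test_that("silhouette matches a direct evaluation of its formula", {
  set.seed(52)
  emb <- rbind(c(0, 0.2, 0.1, 5, 5.1, 5.3), c(0, 0.1, 0.2, 0, 0.1, 0.3))
  lab <- c(1, 1, 1, 2, 2, 2)
  D <- as.matrix(stats::dist(t(emb)))
  widths <- vapply(1:6, function(i) {
    a <- mean(D[i, lab == lab[i] & seq_len(6) != i])
    b <- min(vapply(setdiff(unique(lab), lab[i]), function(cl)
      mean(D[i, lab == cl]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_equal(silhouetteScore(emb, lab), mean(widths), tolerance = 1e-10)

  # well separated tight blobs approach 1
  emb2 <- cbind(matrix(rnorm(20, 0, 0.01), 2), matrix(rnorm(20, 50, 0.01), 2))
  expect_gte(silhouetteScore(emb2, rep(1:2, each = 10)), 0.95)

  # duplicated points split across clusters score non-positive
  emb3 <- matrix(rep(c(0, 1), 4), 1)
  expect_lte(silhouetteScore(emb3, c(1, 1, 2, 2, 1, 1, 2, 2)), 0)

  expect_error(silhouetteScore(emb, rep(1, 6)), "2 clusters")
})

test_that("kNN purity counts label-sharing neighbours, self excluded", {
  emb <- matrix(c(0, 0.1, 1, 1.1), 1)
  expect_equal(knnPurity(emb, c("A", "A", "B", "B"), kNeighbors = 1), 1)
  expect_equal(knnPurity(emb, c("A", "B", "A", "B"), kNeighbors = 1), 0)
  # 4-point hand case with k = 2: each point has one matching neighbour
  expect_equal(knnPurity(emb, c("A", "A", "B", "B"), kNeighbors = 2), 0.5)
  expect_error(knnPurity(emb, c("A", "A", "B", "B"), kNeighbors = 4),
               "smaller")

  # independence null: purity of random balanced labels is about 1/2
  set.seed(53)
  embR <- matrix(rnorm(2 * 1000), 2)
  labR <- sample(rep(c("A", "B"), 500))
  expect_lt(abs(knnPurity(embR, labR, kNeighbors = 20) - 0.5), 0.05)
})

test_that("purity and silhouette are invariant to orthogonal maps", {
  set.seed(54)
  emb <- matrix(rnorm(3 * 30), 3)
  lab <- rep(1:3, each = 10)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  expect_equal(silhouetteScore(Q %*% emb, lab), silhouetteScore(emb, lab),
               tolerance = 1e-9)
  expect_equal(knnPurity(Q %*% emb, lab, 5), knnPurity(emb, lab, 5),
               tolerance = 1e-12)
})

test_that("Leiden clustering recovers well-separated blobs", {
  set.seed(55)
  emb <- cbind(matrix(rnorm(2 * 15, 0, 0.1), 2),
               matrix(rnorm(2 * 15, 10, 0.1), 2))
  truth <- rep(1:2, each = 15)
  for (res in c(0.1, 0.5, 1)) {
    cl <- clusterEmbedding(emb, kNeighbors = 14, resolution = res, seed = 1)
    expect_equal(length(unique(cl)), 2)
    expect_equal(ariScore(truth, cl), 1)
  }
  expect_identical(clusterEmbedding(emb, 14, 0.5, seed = 2),
                   clusterEmbedding(emb, 14, 0.5, seed = 2))
})

test_that("the resolution sweep returns a curve and its maximum", {
  set.seed(56)
  emb <- cbind(matrix(rnorm(2 * 15, 0, 0.1), 2),
               matrix(rnorm(2 * 15, 8, 0.1), 2),
               matrix(c(rnorm(15, 0, 0.1), rnorm(15, 8, 0.1)), 2,
                      byrow = TRUE))
  truth <- rep(1:3, each = 15)
  sw <- ariAcrossResolutions(emb, truth, resolutions = seq(0.2, 1, 0.2),
                             kNeighbors = 14, seed = 1)
  expect_length(sw$ari, 5)
  expect_equal(sw$maxARI, max(sw$ari))
  expect_equal(sw$maxARI, 1)

  # constant embedding carries no information about the labels
  embC <- matrix(1, 2, 45)
  swC <- ariAcrossResolutions(embC, truth, resolutions = c(0.5, 1),
                              kNeighbors = 10, seed = 1)
  expect_lt(abs(swC$maxARI), 0.1)

  # monotone relabeling of the truth changes nothing
  sw2 <- ariAcrossResolutions(emb, c("a", "b", "c")[truth],
                              resolutions = seq(0.2, 1, 0.2),
                              kNeighbors = 14, seed = 1)
  expect_equal(sw2$ari, sw$ari)
})

test_that("specificity scores follow the within/outside mean formula", {
  # factor1: a = 0.4, b = 0.1; factor2: a = 0.5 (the max); score1 = 0.6
  W <- rbind(f1 = c(0.4, 0.4, 0.1, 0.1),
             f2 = c(0.5, 0.5, 0.3, 0.3))
  lab <- c("T", "T", "O", "O")
  tab <- specificityTable(W, lab)
  r <- tab[tab$cellType == "T" & tab$factor == "f1", ]
  expect_equal(r$a, 0.4)
  expect_equal(r$b, 0.1)
  expect_equal(r$score, 0.6, tolerance = 1e-12)

  # a factor active only inside the type with the top mean scores 1
  W2 <- rbind(f1 = c(1, 1, 0, 0), f2 = c(0.2, 0.2, 0.2, 0.2))
  tab2 <- specificityTable(W2, lab)
  expect_equal(tab2[tab2$cellType == "T" & tab2$factor == "f1", "score"], 1)
  # a == b scores 0
  expect_equal(tab2[tab2$cellType == "T" & tab2$factor == "f2", "score"], 0)

  # the active fraction uses the 1e-3 threshold on absolute weights
  W3 <- rbind(f1 = c(1e-4, 0.5, 0.2, 0.1))
  tab3 <- specificityTable(W3, lab)
  expect_equal(tab3[tab3$cellType == "T", "activeFraction"], 0.5)
})

test_that("specificity is bounded by 1 for arbitrary nonnegative input", {
  set.seed(57)
  for (rep in 1:20) {
    W <- matrix(rexp(5 * 30), 5, 30)
    lab <- sample(3, 30, replace = TRUE)
    expect_true(all(specificityTable(W, lab)$score <= 1 + 1e-12))
  }
})

test_that("signed factors are split into positive and negative parts", {
  W <- rbind(f1 = c(1, -1, 0.5, -0.5))
  sp <- splitSignedFactors(W)
  expect_equal(nrow(sp), 2)
  expect_true(all(sp >= 0))
  expect_equal(unname(sp["f1+", ]), c(1, 0, 0.5, 0))
  expect_equal(unname(sp["f1-", ]), c(0, 1, 0, 0.5))
  lab <- c("T", "T", "O", "O")
  tab <- specificityTable(W, lab)
  expect_true(all(c("f1+", "f1-") %in% tab$factor))
})
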