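#' Adjusted Rand Index
#'
#' Chance-corrected agreement between two partitions via the standard
#' contingency-table closed form,
#' \eqn{(RI - E[RI]) / (\max(RI) - E[RI])}: 1 for identical partitions,
#' about 0 for independent ones, and possibly negative for worse than
#' chance.
#'
#' @param truth,pred Label vectors of equal length (>= 2); any atomic type.
#' @return The ARI, in \[-1, 1\].
#' @export
ariScore <- function(truth, pred) {
  if (length(truth) != length(pred))
    stop("truth and pred must have the same length")
  if (length(truth) < 2) stop("need at least 2 observations")
  tab <- table(truth, pred)
  choose2 <- function(x) x * (x - 1) / 2
  sumIJ <- sum(choose2(tab))
  sumA <- sum(choose2(rowSums(tab)))
  sumB <- sum(choose2(colSums(tab)))
  nPairs <- choose2(sum(tab))
  expected <- sumA * sumB / nPairs
  maxIndex <- (sumA + sumB) / 2
  if (abs(maxIndex - expected) < .Machine$double.eps * 4) {
    return(1)  # both partitions trivial and identical in pair structure
  }
  (sumIJ - expected) / (maxIndex - expected)
}

#' Mean silhouette width of an embedding
#'
#' Mean over cells of \eqn{(b - a)/\max(a, b)}, with \eqn{a} the mean
#' distance to the cell's own cluster and \eqn{b} the mean distance to the
#' nearest other cluster; euclidean distances on the embedding columns.
#'
#' @param embedding k-by-n matrix (cells in columns).
#' @param labels Cluster labels, length n, at least 2 distinct values.
#' @return Mean silhouette width, in \[-1, 1\].
#' @export
silhouetteScore <- function(embedding, labels) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2)
    stop("silhouette requires at least 2 clusters")
  d <- stats::dist(t(embedding))
  sil <- cluster::silhouette(as.integer(droplevels(labels)), d)
  mean(sil[, "sil_width"])
}

#' kNN purity of an embedding
#'
#' Average over cells of the proportion of the cell's `kNeighbors` nearest
#' neighbours (euclidean distance on embedding columns, self excluded,
#' distance ties broken by cell index) that share the cell's label.
#'
#' @param embedding k-by-n matrix (cells in columns).
#' @param labels Label vector of length n.
#' @param kNeighbors Neighbourhood size, must be below n (default 20, the
#'   same neighbourhood used for the clustering graph).
#' @return Purity in \[0, 1\].
#' @export
knnPurity <- function(embedding, labels, kNeighbors = 20) {
  n <- ncol(embedding)
  if (kNeighbors >= n)
    stop("kNeighbors (", kNeighbors, ") must be smaller than the number ",
         "of cells (", n, ")")
  labels <- as.character(labels)
  D <- as.matrix(stats::dist(t(embedding)))
  mean(vapply(seq_len(n), function(i) {
    ord <- order(D[i, -i], seq_len(n - 1))[seq_len(kNeighbors)]
    nbr <- seq_len(n)[-i][ord]
    mean(labels[nbr] == labels[i])
  }, numeric(1)))
}

# Shared euclidean kNN graph over embedding columns.
.knnGraph <- function(embedding, kNeighbors = 20) {
  n <- ncol(embedding)
  if (n <= kNeighbors)
    stop("need more cells than kNeighbors for the kNN graph")
  D <- as.matrix(stats::dist(t(embedding)))
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    ord <- order(D[i, -i], seq_len(n - 1))[seq_len(kNeighbors)]
    cbind(i, seq_len(n)[-i][ord])
  }))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::simplify(g)
}

#' Leiden clustering of an embedding
#'
#' Builds the euclidean kNN graph (k = 20 by default) over the embedding
#' columns and partitions it with the Leiden algorithm under modularity at
#' the given resolution. Seeded for reproducibility.
#'
#' @param embedding k-by-n matrix (cells in columns).
#' @param kNeighbors Neighbourhood size of the graph.
#' @param resolution Leiden resolution parameter.
#' @param seed Seed for the (stochastic) Leiden refinement.
#' @return Integer vector of community labels, length n.
#' @export
clusterEmbedding <- function(embedding, kNeighbors = 20, resolution = 1,
                             seed = 0) {
  g <- .knnGraph(embedding, kNeighbors)
  .withSeed(seed, {
    cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution,
                                 n_iterations = 5)
    igraph::membership(cl)
  })
}

#' ARI across Leiden resolutions
#'
#' Clusters the embedding at each resolution and scores every clustering
#' against the ground-truth labels; the maximum over the sweep is the
#' headline number for controlled settings (high resolutions necessarily
#' overcluster three-population data).
#'
#' @param embedding k-by-n matrix (cells in columns).
#' @param truth Ground-truth labels, length n.
#' @param resolutions Resolution grid (default 0.1 to 2 in steps of 0.1).
#' @param kNeighbors,seed Passed to [clusterEmbedding()].
#' @return List with `resolutions`, per-resolution `ari`, and `maxARI`.
#' @export
ariAcrossResolutions <- function(embedding, truth,
                                 resolutions = seq(0.1, 2, by = 0.1),
                                 kNeighbors = 20, seed = 0) {
  aris <- vapply(resolutions, function(r) {
    ariScore(truth, clusterEmbedding(embedding, kNeighbors, r, seed))
  }, numeric(1))
  list(resolutions = resolutions, ari = aris, maxARI = max(aris))
}

#' Factor-by-cell-type specificity table
#'
#' For every factor \eqn{i} and cell type: the fraction of in-type cells
#' with \eqn{|w| > } `threshold`, the mean weight inside the type
#' (\eqn{a_i}), the mean weight outside (\eqn{b_i}), and the score
#' \deqn{\mathrm{specificity}_i = (a_i - b_i) / \max_j a_j,}
#' with the max over all factors of that cell type, so the score is
#' bounded by 1 (attained by a factor active only inside the type and
#' carrying the largest within-type mean). For models with signed factors
#' (the NMF-free baselines), each factor is first split into its positive
#' and negative parts; nonnegative models are unaffected.
#'
#' @param x A [FactorModel-class] or a k-by-n embedding matrix.
#' @param labels Cell-type labels covering all cells.
#' @param threshold Activity threshold on absolute weights (default 1e-3).
#' @return A `data.frame` with columns `factor`, `cellType`,
#'   `activeFraction`, `a`, `b`, `score`.
#' @export
specificityTable <- function(x, labels, threshold = 1e-3) {
  W <- if (methods::is(x, "FactorModel")) embedding(x) else as.matrix(x)
  signed <- any(W < 0)
  if (signed) W <- splitSignedFactors(W)
  labels <- as.factor(labels)
  if (length(labels) != ncol(W))
    stop("labels must cover all cells")
  if (any(table(labels) == 0) || nlevels(labels) != nlevels(droplevels(labels)))
    stop("cell type with zero cells")
  if (is.null(rownames(W)))
    rownames(W) <- paste0("factor", seq_len(nrow(W)))
  out <- do.call(rbind, lapply(levels(labels), function(ct) {
    inT <- labels == ct
    a <- rowMeans(W[, inT, drop = FALSE])
    b <- rowMeans(W[, !inT, drop = FALSE])
    if (all(!inT) || all(inT)) stop("cell type partition is degenerate")
    amax <- max(a)
    if (amax <= 0)
      stop("all factors have zero mean weight within '", ct, "'")
    data.frame(factor = rownames(W), cellType = ct,
               activeFraction = rowMeans(abs(W[, inT, drop = FALSE]) >
                                           threshold),
               a = a, b = b, score = (a - b) / amax,
               row.names = NULL)
  }))
  out
}

#' Split signed factors into positive and negative parts
#'
#' Each row \eqn{w} of a signed factor matrix becomes two nonnegative rows
#' \eqn{w_+} and \eqn{w_-} (suffixe `+`/`-`), the convention used when
#' scoring methods whose factors are not sign-constrained.
#'
#' @param W Factors-by-cells matrix.
#' @return A matrix with twice the rows, all nonnegative.
#' @export
splitSignedFactors <- function(W) {
  W <- as.matrix(W)
  if (is.null(rownames(W)))
    rownames(W) <- paste0("factor", seq_len(nrow(W)))
  pos <- pmax(W, 0)
  neg <- pmax(-W, 0)
  rownames(pos) <- paste0(rownames(W), "+")
  rownames(neg) <- paste0(rownames(W), "-")
  rbind(pos, neg)
}

#' Evaluation report for a fitted model
#'
#' Convenience wrapper computing the embedding/clustering metrics in one
#' go: silhouette on the ground-truth labels, ARI across Leiden
#' resolutions (with the maximum), kNN purity, and the per-factor
#' specificity table.
#'
#' @param model A [FactorModel-class].
#' @param labels Ground-truth cell labels.
#' @param resolutions Resolution grid for the ARI sweep.
#' @param kNeighbors Neighbourhood size for purity and the cluster graph.
#' @param seed Seed for the Leiden sweep.
#' @return List with `silhouette`, `ariCurve`, `maxARI`, `knnPurity` and
#'   `specificity`.
#' @export
evaluateModel <- function(model, labels,
                          resolutions = seq(0.1, 2, by = 0.1),
                          kNeighbors = 20, seed = 0) {
  W <- embedding(model)
  sweep <- ariAcrossResolutions(W, labels, resolutions, kNeighbors, seed)
  list(silhouette = silhouetteScore(W, labels),
       ariCurve = data.frame(resolution = sweep$resolutions,
                             ari = sweep$ari),
       maxARI = sweep$maxARI,
       knnPurity = knnPurity(W, labels, kNeighbors),
       specificity = specificityTable(model, labels))
}
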