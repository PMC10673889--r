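#' Integrative NMF baseline
#'
#' Concatenates the features of all modalities row-wise into one matrix
#' \eqn{A} (\eqn{m = \sum_p m_p} rows) and approximately solves
#' \deqn{\min_{H \ge 0,\, W \ge 0} \|A - HW\|_2}
#' by multiplicative updates (Lee-Seung, with a 1e-10 denominator guard).
#' The objective is non-increasing per iteration. After fitting, columns
#' of \eqn{H} are normalized to unit L2 norm (with the inverse scaling
#' applied to \eqn{W}) purely as a reporting convention. No simplex
#' constraint is imposed: this is the Euclidean baseline the transport
#' model is compared against.
#'
#' @param dataset A [MultiOmicsDataset-class]; views may be raw or
#'   preprocessed, only nonnegativity is required.
#' @param k Number of latent dimensions (default 30, the usual choice for
#'   heterogeneous data; must not exceed `min(m, n)`).
#' @param maxIter Iteration cap.
#' @param tol Relative objective-change stopping tolerance.
#' @param seed Seed for the random nonnegative initialization.
#' @return A [FactorModel-class] with `simplex = FALSE`; the single
#'   concatenated dictionary is split back per modality. The loss trace
#'   holds `||A - HW||_F` per iteration.
#' @export
integrativeNMF <- function(dataset, k = 30, maxIter = 500, tol = 1e-6,
                           seed = 0) {
  nms <- viewNames(dataset)
  mats <- lapply(nms, function(nm) as.matrix(getView(dataset, nm)@matrix))
  A <- do.call(rbind, mats)
  m <- nrow(A); n <- ncol(A)
  if (k > min(m, n))
    stop("k (", k, ") exceeds min(features, cells) = ", min(m, n))
  guard <- 1e-10
  init <- .withSeed(seed, list(
    H = matrix(stats::runif(m * k, 0.1, 1), m, k) * sqrt(mean(A) / k),
    W = matrix(stats::runif(k * n, 0.1, 1), k, n) * sqrt(mean(A) / k)))
  H <- init$H; W <- init$W
  trace <- numeric(0)
  objPrev <- Inf
  for (it in seq_len(maxIter)) {
    H <- H * (A %*% t(W)) / (H %*% W %*% t(W) + guard)
    W <- W * (t(H) %*% A) / (t(H) %*% H %*% W + guard)
    obj <- sqrt(sum((A - H %*% W)^2))
    trace <- c(trace, obj)
    if (is.finite(objPrev) && abs(objPrev - obj) <= tol * max(objPrev, guard))
      break
    objPrev <- obj
  }
  nrm <- sqrt(colSums(H^2))
  nrm[nrm == 0] <- 1
  H <- sweep(H, 2, nrm, "/")
  W <- sweep(W, 1, nrm, "*")  # rows of W absorb the H column scaling
  rownames(H) <- rownames(A)
  colnames(W) <- colnames(A)
  fac <- paste0("factor", seq_len(k))
  colnames(H) <- fac
  rownames(W) <- fac
  ms <- vapply(mats, nrow, integer(1))
  ends <- cumsum(ms)
  starts <- c(1, utils::head(ends, -1) + 1)
  dicts <- lapply(seq_along(nms), function(p)
    H[starts[p]:ends[p], , drop = FALSE])
  names(dicts) <- nms
  methods::new("FactorModel", dictionaries = dicts, embedding = W,
               k = as.integer(k),
               config = list(method = "nmf", k = k, maxIter = maxIter,
                             tol = tol, seed = seed),
               lossTrace = trace, simplex = FALSE)
}
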