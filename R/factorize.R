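#' Model configuration
#'
#' Collects every tunable of the optimal-transport factorization. The
#' unscaled sparsity parameters are \eqn{\tilde\rho_p} per modality
#' (defaults: rna 0.01, adt 0.01, atac 0.1) and \eqn{\tilde\mu}
#' (default 0.001); [scaleRegularization()] turns them into the effective
#' \eqn{\rho_p} and \eqn{\mu} once the data dimensions are known. `k = 5`
#' suits three-population/controlled data; heterogeneous datasets are
#' typically run with `k = 50`.
#'
#' @param k Number of latent dimensions (>= 2).
#' @param rhoTilde Named vector of per-modality unscaled dictionary
#'   sparsity parameters; views are matched by name, then by modality kind
#'   (rna/atac/adt), then fall back to `rhoTildeDefault`.
#' @param rhoTildeDefault Fallback \eqn{\tilde\rho} for unmatched views.
#' @param muTilde Unscaled embedding sparsity parameter.
#' @param eps Entropic regularization of the transport loss.
#' @param innerMaxIter,innerTol,innerFactr,historySize L-BFGS settings for
#'   the smooth dual subproblems: iteration cap, projected-gradient
#'   tolerance, relative objective-change stopping factor (in units of
#'   machine precision, the L-BFGS-B convention; the stiff negentropy
#'   conjugate makes objective-change the practical criterion), and
#'   limited-memory history.
#' @param outerMaxIter,lossRTol Outer alternation cap and relative
#'   loss-change stopping tolerance.
#' @param auditEvery Run a full Sinkhorn-based primal loss audit every this
#'   many outer iterations (the trace itself reuses the cheap dual value).
#' @param seed Integer seed controlling the initialization.
#' @return A named list (class `"otOmicsConfig"`).
#' @export
modelConfig <- function(k = 5,
                        rhoTilde = c(rna = 0.01, adt = 0.01, atac = 0.1),
                        rhoTildeDefault = 0.01,
                        muTilde = 0.001,
                        eps = 0.05,
                        innerMaxIter = 3000, innerTol = 1e-7,
                        innerFactr = 1e7, historySize = 10,
                        outerMaxIter = 100, lossRTol = 1e-5,
                        auditEvery = 10,
                        seed = 0) {
  stopifnot(k >= 2, muTilde > 0, eps > 0, all(rhoTilde > 0),
            rhoTildeDefault > 0)
  structure(list(k = as.integer(k), rhoTilde = rhoTilde,
                 rhoTildeDefault = rhoTildeDefault, muTilde = muTilde,
                 eps = eps, innerMaxIter = innerMaxIter,
                 innerTol = innerTol, innerFactr = innerFactr,
                 historySize = historySize,
                 outerMaxIter = outerMaxIter, lossRTol = lossRTol,
                 auditEvery = auditEvery, seed = as.integer(seed)),
            class = "otOmicsConfig")
}

.rhoTildeFor <- function(config, viewName) {
  rt <- config$rhoTilde
  if (viewName %in% names(rt)) return(rt[[viewName]])
  kind <- .modalityKind(viewName)
  if (kind %in% names(rt)) return(rt[[kind]])
  config$rhoTildeDefault
}

#' Scale the sparsity parameters to the data dimensions
#'
#' \deqn{\rho_p = \tilde\rho_p / (\log(m_p)\, k), \qquad
#'       \mu = \tilde\mu / (\log(k)\, n)}
#' which makes the unscaled parameters comparable across omics and
#' datasets. Natural logarithms throughout; `k = 1` is rejected since
#' \eqn{\log k} vanishes.
#'
#' @param config A [modelConfig()] list.
#' @param dataset A [MultiOmicsDataset-class].
#' @return List with `rho` (named per-view vector) and `mu`.
#' @export
scaleRegularization <- function(config, dataset) {
  if (config$k < 2) stop("k must be at least 2 (log(k) = 0 for k = 1)")
  n <- nCells(dataset)
  rho <- vapply(viewNames(dataset), function(nm) {
    mp <- nrow(getView(dataset, nm)@matrix)
    .rhoTildeFor(config, nm) / (log(mp) * config$k)
  }, numeric(1))
  names(rho) <- viewNames(dataset)
  list(rho = rho, mu = config$muTilde / (log(config$k) * n))
}

.simplexMatrices <- function(dataset) {
  lapply(viewNames(dataset), function(nm) {
    v <- getView(dataset, nm)
    A <- as.matrix(v@matrix)
    cs <- colSums(A)
    if (any(abs(cs - 1) > 1e-6))
      stop("view '", nm, "': column ", which.max(abs(cs - 1)),
           " is off the simplex; run toSimplex()/preprocessDataset() first")
    A
  })
}

.buildContexts <- function(As, names, eps) {
  lapply(seq_along(As), function(p) {
    cc <- cosineCost(As[[p]])
    if (length(cc$kept) < nrow(As[[p]]))
      stop("view '", names[p], "' has zero-norm features after ",
           "preprocessing; remove them before fitting")
    otContext(cc$cost, eps = eps, modality = names[p])
  })
}

# L-BFGS wrapper with a value/gradient cache (optim asks for fn and gr at
# the same point back to back).
.lbfgs <- function(par0, fg, control) {
  env <- new.env(parent = emptyenv())
  ask <- function(par) {
    if (is.null(env$par) || length(par) != length(env$par) ||
        any(par != env$par)) {
      r <- fg(par)
      if (!is.finite(r$value))
        stop("non-finite dual objective; eps may be too small for the ",
             "cost scale, or the cost is degenerate")
      env$value <- r$value
      env$grad <- r$grad
      env$par <- par
    }
    invisible(NULL)
  }
  res <- stats::optim(par0,
                      fn = function(p) { ask(p); env$value },
                      gr = function(p) { ask(p); env$grad },
                      method = "L-BFGS-B",
                      control = list(maxit = control$innerMaxIter,
                                     lmm = control$historySize,
                                     pgtol = control$innerTol,
                                     factr = control$innerFactr))
  res
}

#' Dictionary update (one modality)
#'
#' Minimizes the smooth dual of the dictionary subproblem over the dual
#' variable \eqn{G^{(p)}} with L-BFGS,
#' \deqn{\min_{G} \sum_j OT^\star_\varepsilon(g_j, a_j)
#'   + \rho_p (-E)^\star(-G W^\top / \rho_p),}
#' then recovers the primal dictionary
#' \eqn{H^{(p)} = \mathrm{softmax}(-G W^\top / \rho_p)}, whose columns lie
#' on the simplex by construction.
#'
#' @param A Features-by-cells matrix of simplex columns (the data view).
#' @param W Current k-by-cells embedding (columns on the simplex).
#' @param ctx [OTContext-class] for the modality.
#' @param rho Effective dictionary sparsity parameter \eqn{\rho_p}.
#' @param G0 Optional warm-start dual matrix (features x cells).
#' @param control Optimizer settings; missing entries default to
#'   [modelConfig()].
#' @return List with `H`, the dual matrix `G`, the dual objective `value`
#'   and the optimizer's `convergence` code.
#' @export
updateH <- function(A, W, ctx, rho, G0 = NULL, control = list()) {
  control <- utils::modifyList(modelConfig(), control)
  m <- nrow(A); n <- ncol(A)
  if (is.null(G0)) G0 <- matrix(0, m, n)
  fg <- function(par) {
    G <- matrix(par, m, n)
    oc <- .otConjBatch(G, A, ctx@cost, ctx@eps, wantGrad = TRUE)
    Y <- -(G %*% t(W)) / rho
    H <- softmaxCols(Y)
    list(value = oc$value + rho * negentropyConjugate(Y),
         grad = as.numeric(oc$grad - H %*% W))
  }
  res <- .lbfgs(as.numeric(G0), fg, control)
  G <- matrix(res$par, m, n)
  H <- softmaxCols(-(G %*% t(W)) / rho)
  rownames(H) <- rownames(A)
  list(H = H, G = G, value = res$value, convergence = res$convergence)
}

#' Embedding update (all modalities jointly)
#'
#' Minimizes the joint smooth dual over the dual variables of every
#' modality,
#' \deqn{\min_{G^{(1..d)}} \sum_p \sum_j OT^\star_\varepsilon(g^{(p)}_j,
#'   a^{(p)}_j) + d\mu\,(-E)^\star\!\Big(-\tfrac{1}{d\mu} \sum_p
#'   H^{(p)\top} G^{(p)}\Big),}
#' then recovers \eqn{W = \mathrm{softmax}(-\frac{1}{d\mu} \sum_p
#' H^{(p)\top} G^{(p)})}.
#'
#' @param As List of features-by-cells simplex matrices, one per modality.
#' @param Hs List of current dictionaries (columns on the simplex).
#' @param ctxs List of [OTContext-class] objects, aligned with `As`.
#' @param mu Effective embedding sparsity parameter.
#' @param G0s Optional list of warm-start dual matrices.
#' @param control Optimizer settings; missing entries default to
#'   [modelConfig()].
#' @return List with `W`, the dual matrices `Gs`, the dual objective
#'   `value` and the optimizer's `convergence` code.
#' @export
updateW <- function(As, Hs, ctxs, mu, G0s = NULL, control = list()) {
  control <- utils::modifyList(modelConfig(), control)
  d <- length(As)
  ms <- vapply(As, nrow, integer(1))
  n <- ncol(As[[1]])
  k <- ncol(Hs[[1]])
  if (is.null(G0s)) G0s <- lapply(ms, function(m) matrix(0, m, n))
  sizes <- ms * n
  offs <- c(0, cumsum(sizes))
  dmu <- d * mu
  fg <- function(par) {
    val <- 0
    M <- matrix(0, k, n)
    Rs <- vector("list", d)
    Gs <- vector("list", d)
    for (p in seq_len(d)) {
      G <- matrix(par[(offs[p] + 1):offs[p + 1]], ms[p], n)
      Gs[[p]] <- G
      oc <- .otConjBatch(G, As[[p]], ctxs[[p]]@cost, ctxs[[p]]@eps,
                         wantGrad = TRUE)
      val <- val + oc$value
      Rs[[p]] <- oc$grad
      M <- M + crossprod(Hs[[p]], G)
    }
    Y <- -M / dmu
    Wn <- softmaxCols(Y)
    grad <- unlist(lapply(seq_len(d),
                          function(p) as.numeric(Rs[[p]] - Hs[[p]] %*% Wn)),
                   use.names = FALSE)
    list(value = val + dmu * negentropyConjugate(Y), grad = grad)
  }
  res <- .lbfgs(unlist(lapply(G0s, as.numeric), use.names = FALSE), fg,
                control)
  Gs <- lapply(seq_len(d), function(p)
    matrix(res$par[(offs[p] + 1):offs[p + 1]], ms[p], n))
  M <- Reduce(`+`, lapply(seq_len(d), function(p) crossprod(Hs[[p]], Gs[[p]])))
  W <- softmaxCols(-M / dmu)
  colnames(W) <- colnames(As[[1]])
  list(W = W, Gs = Gs, value = res$value, convergence = res$convergence)
}

#' Full primal loss of a factor model
#'
#' Evaluates, by Sinkhorn at the requested tolerance,
#' \deqn{\sum_p \Big( \sum_j OT_\varepsilon(H^{(p)} w_j, a^{(p)}_j)
#'   - \rho_p E(H^{(p)}) - \mu E(W) \Big),}
#' the objective the alternating updates minimize (note the embedding
#' entropy is counted once per modality, matching the joint dual and its
#' softmax recovery).
#'
#' @param model A [FactorModel-class] with simplex columns.
#' @param dataset The dataset the model was fitted on (views on the
#'   simplex).
#' @param rho,mu Effective sparsity parameters; recomputed from the
#'   model's config when `NULL`.
#' @param tol,maxIter Sinkhorn settings for the reconstruction terms.
#' @return The loss (a single number).
#' @export
totalLoss <- function(model, dataset, rho = NULL, mu = NULL,
                      tol = 1e-6, maxIter = 2000) {
  cfg <- utils::modifyList(modelConfig(), model@config)
  cfg$k <- model@k
  if (is.null(rho) || is.null(mu)) {
    sc <- scaleRegularization(cfg, dataset)
    if (is.null(rho)) rho <- sc$rho
    if (is.null(mu)) mu <- sc$mu
  }
  As <- .simplexMatrices(dataset)
  nms <- viewNames(dataset)
  W <- model@embedding
  if (any(abs(colSums(W) - 1) > 1e-6))
    stop("embedding columns are off the simplex")
  loss <- 0
  d <- length(As)
  for (p in seq_len(d)) {
    H <- model@dictionaries[[nms[p]]]
    if (any(abs(colSums(H) - 1) > 1e-6))
      stop("dictionary '", nms[p], "' columns are off the simplex")
    cc <- cosineCost(As[[p]])
    X <- H %*% W
    vals <- .sinkhornValues(X, As[[p]], cc$cost, cfg$eps, tol, maxIter)
    loss <- loss + sum(vals) - rho[[nms[p]]] * shannonEntropy(H) -
      mu * shannonEntropy(W)
  }
  loss
}

#' Fit the optimal-transport factor model
#'
#' Alternates dictionary updates (every modality) and the joint embedding
#' update until the relative loss change drops below `lossRTol` or
#' `outerMaxIter` is reached. Dual variables are warm-started from the
#' previous outer iteration. The recorded trace reuses the dual objective
#' of the embedding step (equal to the primal loss at inner convergence by
#' strong duality); a full Sinkhorn audit runs every `auditEvery`
#' iterations and its largest discrepancy is kept in the model config as
#' `auditDrift`. The fit is deterministic given the seed, and aborts with
#' diagnostics if the loss increases relatively by more than 1e-6 for
#' three consecutive outer iterations.
#'
#' @param dataset A [MultiOmicsDataset-class] whose views are all on the
#'   simplex (see [preprocessDataset()] / [toSimplex()]).
#' @param config A [modelConfig()] list.
#' @param verbose Print per-iteration losses.
#' @return A [FactorModel-class].
#' @examples
#' \donttest{
#' ds <- simulateMultiOmics(nCells = c(20, 20, 20), seed = 1)
#' ds <- preprocessDataset(ds, nTopRNA = 50, nTopATAC = 50)
#' fit <- fitFactorModel(ds, modelConfig(k = 3, outerMaxIter = 10))
#' }
#' @export
fitFactorModel <- function(dataset, config = modelConfig(),
                           verbose = FALSE) {
  config <- utils::modifyList(modelConfig(), unclass(config))
  As <- .simplexMatrices(dataset)
  nms <- viewNames(dataset)
  d <- length(As)
  n <- ncol(As[[1]])
  k <- config$k
  sc <- scaleRegularization(config, dataset)
  rho <- sc$rho
  mu <- sc$mu
  ctxs <- .buildContexts(As, nms, config$eps)

  # Seeded, cell-order-equivariant initialization: the dual warm start
  # varies only by feature, and the initial embedding is a seeded random
  # projection of the first view's columns (so permuting cells permutes
  # the fit exactly).
  rs <- .withSeed(config$seed, {
    zs <- lapply(As, function(A) stats::rnorm(nrow(A), sd = 0.1))
    R <- matrix(stats::rnorm(k * nrow(As[[1]])), k, nrow(As[[1]]))
    list(zs = zs, R = R)
  })
  Gs <- lapply(seq_len(d), function(p)
    matrix(rs$zs[[p]], nrow(As[[p]]), n))
  S0 <- rs$R %*% As[[1]]
  W <- softmaxCols(S0 / (stats::sd(S0) + 1e-12) * 0.1)

  ctl <- config
  trace <- numeric(0)
  auditDrift <- 0
  nIncrease <- 0L
  Hs <- vector("list", d)
  for (it in seq_len(config$outerMaxIter)) {
    for (p in seq_len(d)) {
      up <- updateH(As[[p]], W, ctxs[[p]], rho[[p]], G0 = Gs[[p]],
                    control = ctl)
      Hs[[p]] <- up$H
      Gs[[p]] <- up$G
    }
    uw <- updateW(As, Hs, ctxs, mu, G0s = Gs, control = ctl)
    W <- uw$W
    Gs <- uw$Gs
    loss <- -uw$value -
      sum(vapply(seq_len(d),
                 function(p) rho[[p]] * shannonEntropy(Hs[[p]]),
                 numeric(1)))
    trace <- c(trace, loss)
    if (verbose)
      message(sprintf("outer %3d  loss %.8g", it, loss))
    if (it > 1) {
      prev <- trace[it - 1]
      rel <- (loss - prev) / max(abs(prev), 1e-12)
      nIncrease <- if (rel > 1e-6) nIncrease + 1L else 0L
      if (nIncrease >= 3L)
        stop("loss increased for 3 consecutive outer iterations ",
             "(last relative increase ", signif(rel, 3),
             "); consider raising innerMaxIter or eps")
      if (abs(rel) < config$lossRTol) break
    }
    if (it %% config$auditEvery == 0) {
      names(Hs) <- nms
      mdl <- methods::new("FactorModel", dictionaries = Hs, embedding = W,
                          k = as.integer(k), config = unclass(config),
                          lossTrace = trace, simplex = TRUE)
      audit <- suppressWarnings(
        totalLoss(mdl, dataset, rho = rho, mu = mu, tol = 1e-5,
                  maxIter = 5000))
      auditDrift <- max(auditDrift, abs(audit - loss) /
                          max(abs(audit), 1e-12))
    }
  }
  names(Hs) <- nms
  fac <- paste0("factor", seq_len(k))
  rownames(W) <- fac
  for (p in seq_len(d)) colnames(Hs[[p]]) <- fac
  cfgOut <- unclass(config)
  cfgOut$rho <- rho
  cfgOut$mu <- mu
  cfgOut$auditDrift <- auditDrift
  methods::new("FactorModel", dictionaries = Hs, embedding = W,
               k = as.integer(k), config = cfgOut, lossTrace = trace,
               simplex = TRUE)
}

# Evaluate expr with a temporary RNG state seeded by `seed`.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
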