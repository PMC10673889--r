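#' Simulate a three-population paired multi-omics dataset
#'
#' Generates two coupled count views ("rna"-like and "atac"-like) over the
#' same cells, with three separable cell populations and a controlled
#' overall sparsity. Each population activates its own block of feature
#' programs in both views (Gamma-distributed program means, Poisson
#' counts); a seeded random mask then raises the zero fraction to the
#' requested sparsity. This is a synthetic stand-in for a joint
#' RNA+chromatin profiling of three well-separated cell lines: it provides
#' separable populations with realistic sparsity, not a distributional
#' model of any real assay.
#'
#' @param nCells Integer vector of the three population sizes.
#' @param nFeatures Named integer vector of per-view feature counts.
#' @param sparsity Target overall zero fraction (in \[0, 1)); realized
#'   sparsity lands within about two percentage points.
#' @param programSize Number of features forming each population's
#'   signature block per view.
#' @param meanHigh,meanLow Gamma means of signature and background
#'   features.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return A [MultiOmicsDataset-class] with population labels
#'   `pop1/pop2/pop3`.
#' @export
simulateMultiOmics <- function(nCells = c(50, 50, 50),
                               nFeatures = c(rna = 100, atac = 100),
                               sparsity = 0.65,
                               programSize = 25,
                               meanHigh = 8, meanLow = 0.6,
                               seed = 0) {
  nCells <- unlist(nCells)          # accept list input from YAML configs
  nFeatures <- unlist(nFeatures)
  if (is.null(names(nFeatures)))    # serialized configs may drop names
    names(nFeatures) <- c("rna", "atac",
                          paste0("view", seq_len(max(0, length(nFeatures) -
                                                       2)) + 2))[
                            seq_along(nFeatures)]
  stopifnot(length(nCells) == 3, all(nCells >= 1),
            sparsity >= 0, sparsity < 1)
  n <- sum(nCells)
  grp <- rep(1:3, times = nCells)
  cells <- sprintf("cell%04d", seq_len(n))
  .withSeed(seed, {
    views <- lapply(seq_along(nFeatures), function(vi) {
      m <- nFeatures[[vi]]
      nm <- names(nFeatures)[vi]
      ps <- min(programSize, floor(m / 3))
      mu <- matrix(meanLow, m, n)
      for (g in 1:3) {
        feats <- ((g - 1) * ps + 1):(g * ps)
        gm <- stats::rgamma(ps, shape = 4, rate = 4 / meanHigh)
        mu[feats, grp == g] <- gm
      }
      X <- matrix(stats::rpois(m * n, as.vector(mu)), m, n)
      z0 <- mean(X == 0)
      if (z0 < sparsity) {
        q <- (sparsity - z0) / (1 - z0)
        X[matrix(stats::runif(m * n) < q, m, n)] <- 0L
      }
      feats <- if (.modalityKind(nm) == "atac")
        sprintf("chr%d:%d-%d", (seq_len(m) - 1L) %% 22L + 1L,
                seq_len(m) * 1000L + 1L, seq_len(m) * 1000L + 500L)
      else sprintf("%s_f%04d", nm, seq_len(m))
      dimnames(X) <- list(feats, cells)
      OmicsView(nm, X)
    })
    names(views) <- names(nFeatures)
    MultiOmicsDataset(views, labels = factor(paste0("pop", grp)))
  })
}

.groupLevel <- function(dataset, group) {
  lv <- levels(dataset@labels)
  if (is.numeric(group)) {
    stopifnot(group >= 1, group <= length(lv))
    return(lv[group])
  }
  if (!group %in% lv) stop("no population named '", group, "'")
  group
}

# Replace the `view` columns of every `from`-population cell with the
# column of a uniformly resampled (with replacement) `donor` cell.
.replaceProfiles <- function(dataset, view, from, donor, seed) {
  from <- .groupLevel(dataset, from)
  donor <- .groupLevel(dataset, donor)
  iFrom <- which(dataset@labels == from)
  iDonor <- which(dataset@labels == donor)
  if (!length(iFrom) || !length(iDonor))
    stop("population '", if (!length(iFrom)) from else donor, "' is empty")
  pick <- .withSeed(seed, sample(iDonor, length(iFrom), replace = TRUE))
  m <- dataset@views[[view]]@matrix
  m[, iFrom] <- m[, pick, drop = FALSE]
  .replaceViewMatrix(dataset, view, m)
}

#' Controlled setting: populations mixed in RNA
#'
#' Makes populations 1 and 2 indistinguishable in the first (rna-like)
#' view by replacing every population-1 cell's RNA profile with that of a
#' uniformly sampled (with replacement) population-2 cell. The second view
#' is left untouched, so only the joint analysis can separate all three
#' populations.
#'
#' @param dataset A labelled [MultiOmicsDataset-class] (e.g. from
#'   [simulateMultiOmics()]).
#' @param seed Seed for the donor sampling.
#' @param view Name of the view to scramble (default the first view).
#' @return The transformed dataset (labels unchanged).
#' @export
mixInRNA <- function(dataset, seed = 0, view = viewNames(dataset)[1]) {
  .replaceProfiles(dataset, view, from = 1, donor = 2, seed = seed)
}

#' Controlled setting: populations mixed in both views
#'
#' Applies [mixInRNA()] (population 1 takes population-2 RNA profiles) and
#' additionally replaces the second view's profiles of population 3 with
#' those of random population-2 cells. Each view now confuses a different
#' pair of populations; they are only jointly separable.
#'
#' @inheritParams mixInRNA
#' @param views Names of the two views (RNA-like first).
#' @return The transformed dataset.
#' @export
mixInBoth <- function(dataset, seed = 0,
                      views = viewNames(dataset)[1:2]) {
  dataset <- .replaceProfiles(dataset, views[1], from = 1, donor = 2,
                              seed = seed)
  .replaceProfiles(dataset, views[2], from = 3, donor = 2,
                   seed = seed + 1L)
}

#' Controlled setting: extra dropout noise
#'
#' Independently replaces each entry of every view by zero with
#' probability `p` (uniformly over all positions, including existing
#' zeros). Starting from baseline sparsity \eqn{s_0}, the expected final
#' sparsity is \eqn{1 - (1 - s_0)(1 - p)}: from 65% baseline, p of 0.5,
#' 0.7 and 0.9 yields 82%, 90% and 96%.
#'
#' @param dataset A [MultiOmicsDataset-class].
#' @param p Dropout probability in \[0, 1\].
#' @param seed Seed for the dropout mask.
#' @return The sparsified dataset.
#' @export
addDropout <- function(dataset, p, seed = 0) {
  stopifnot(p >= 0, p <= 1)
  .withSeed(seed, {
    for (nm in viewNames(dataset)) {
      m <- dataset@views[[nm]]@matrix
      mask <- matrix(stats::runif(length(m)) < p, nrow(m), ncol(m))
      m[mask] <- 0
      dataset <- .replaceViewMatrix(dataset, nm, m)
    }
    dataset
  })
}

#' Controlled setting: rare population
#'
#' Downsamples one population to `nKeep` uniformly chosen cells
#' (consistently across all views); the other populations are kept whole.
#'
#' @param dataset A labelled [MultiOmicsDataset-class].
#' @param group Population to make rare (level name or index; default the
#'   second population).
#' @param nKeep Number of cells of that population to retain.
#' @param seed Seed for the cell sampling.
#' @return The subsetted dataset.
#' @export
rarePopulation <- function(dataset, group = 2, nKeep = 10, seed = 0) {
  group <- .groupLevel(dataset, group)
  iGrp <- which(dataset@labels == group)
  if (nKeep > length(iGrp))
    stop("nKeep (", nKeep, ") exceeds the size of population '", group,
         "' (", length(iGrp), ")")
  keepGrp <- .withSeed(seed, sort(sample(iGrp, nKeep)))
  keep <- sort(c(setdiff(seq_len(nCells(dataset)), iGrp), keepGrp))
  .subsetCells(dataset, keep)
}

#' Overall zero fraction of a dataset
#'
#' @param dataset A [MultiOmicsDataset-class].
#' @return Fraction of zero entries across all views.
#' @export
datasetSparsity <- function(dataset) {
  zeros <- 0
  total <- 0
  for (nm in viewNames(dataset)) {
    m <- getView(dataset, nm)@matrix
    total <- total + prod(dim(m))
    zeros <- zeros + (prod(dim(m)) - Matrix::nnzero(m))
  }
  zeros / total
}
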