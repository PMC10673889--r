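#' Quality-control filtering of cells
#'
#' Removes cells failing any enabled threshold on the given modality, from
#' **all** views of the dataset so that the paired-cells contract is kept.
#' Thresholds are disabled (`NULL`) by default: the filters exist but carry
#' no default values, so nothing is removed unless a threshold is set.
#'
#' @param dataset A [MultiOmicsDataset-class].
#' @param modality Name of the view the thresholds are evaluated on.
#' @param minCounts,maxCounts Bounds on the per-cell total count.
#' @param minFeatures Minimum number of detected (nonzero) features.
#' @param maxMitoFraction Maximum fraction of counts on mitochondrial
#'   features (feature ids prefixed `"MT-"`); only meaningful for RNA.
#' @return The filtered dataset. Errors if every cell is removed.
#' @export
filterCells <- function(dataset, modality, minCounts = NULL,
                        maxCounts = NULL, minFeatures = NULL,
                        maxMitoFraction = NULL) {
  v <- getView(dataset, modality)
  m <- v@matrix
  keep <- rep(TRUE, ncol(m))
  totals <- Matrix::colSums(m)
  if (!is.null(minCounts)) {
    stopifnot(minCounts >= 0)
    keep <- keep & totals >= minCounts
  }
  if (!is.null(maxCounts)) {
    stopifnot(maxCounts >= 0)
    keep <- keep & totals <= maxCounts
  }
  if (!is.null(minFeatures)) {
    stopifnot(minFeatures >= 0)
    if (minFeatures > nrow(m))
      stop("minFeatures exceeds the number of features (", nrow(m), ")")
    keep <- keep & Matrix::colSums(m > 0) >= minFeatures
  }
  if (!is.null(maxMitoFraction)) {
    stopifnot(maxMitoFraction >= 0)
    mito <- startsWith(rownames(m), "MT-")
    frac <- if (any(mito))
      Matrix::colSums(m[mito, , drop = FALSE]) / pmax(totals, 1e-300)
    else rep(0, ncol(m))
    keep <- keep & frac <= maxMitoFraction
  }
  if (!any(keep)) stop("empty dataset after QC")
  removed <- sum(!keep)
  if (removed > 0)
    message(removed, " cell(s) removed by QC on '", modality, "'")
  .subsetCells(dataset, which(keep))
}

#' Total-count normalization
#'
#' Scales every cell (column) to the same total, 10000 by default.
#'
#' @param view An [OmicsView-class].
#' @param targetSum Positive total each column is scaled to.
#' @return The normalized view.
#' @export
normalizeTotal <- function(view, targetSum = 10000) {
  stopifnot(targetSum > 0)
  cs <- Matrix::colSums(view@matrix)
  if (any(cs == 0)) {
    bad <- colnames(view@matrix)[which(cs == 0)[1L]]
    stop("cell '", bad, "' has zero total count; cannot normalize")
  }
  m <- view@matrix %*% Matrix::Diagonal(x = targetSum / cs)
  dimnames(m) <- dimnames(view@matrix)
  view@matrix <- .maybeSparsify(m)
  view@isSimplex <- abs(targetSum - 1) < 1e-12
  view
}

#' Log transformation
#'
#' Applies \eqn{x \mapsto \log(1 + x)} entrywise.
#'
#' @param view An [OmicsView-class] with nonnegative entries.
#' @return The transformed view.
#' @export
logTransform <- function(view) {
  m <- view@matrix
  if (methods::is(m, "sparseMatrix")) {
    m@x <- log1p(m@x)
  } else {
    m <- log1p(m)
  }
  view@matrix <- m
  view@isSimplex <- FALSE
  view
}

#' Highly variable feature selection
#'
#' Keeps the `nTop` features with the largest normalized dispersion,
#' computed the way the classic single-cell "seurat" flavour does:
#' per-feature dispersion = variance / mean (on the log-normalized data),
#' z-scored within 20 equal-count bins of the feature means. Ties are
#' broken by feature index. The original feature order is preserved among
#' the kept features.
#'
#' @param view A log-normalized [OmicsView-class].
#' @param nTop Number of features to keep (must not exceed the number of
#'   features).
#' @param nBins Number of equal-count mean bins for dispersion
#'   normalization.
#' @return The view restricted to the selected features.
#' @export
selectHVG <- function(view, nTop, nBins = 20) {
  m <- view@matrix
  if (nTop > nrow(m))
    stop("nTop (", nTop, ") exceeds the number of features (", nrow(m), ")")
  disp <- featureDispersion(m, nBins = nBins)
  ord <- order(-disp, seq_along(disp))  # ties broken by feature index
  keep <- sort(ord[seq_len(nTop)])
  view@matrix <- m[keep, , drop = FALSE]
  view
}

#' Normalized feature dispersion
#'
#' The dispersion criterion behind [selectHVG()]: variance over mean per
#' feature, z-scored within equal-count bins of the feature means (features
#' with zero dispersion or singleton bins get a z-score of 0; a bin with
#' zero spread falls back to centering only).
#'
#' @param m Features-by-cells matrix (dense or sparse).
#' @param nBins Number of equal-count mean bins.
#' @return Numeric vector of normalized dispersions, one per feature.
#' @export
featureDispersion <- function(m, nBins = 20) {
  mu <- as.numeric(Matrix::rowSums(m)) / ncol(m)
  ex2 <- as.numeric(Matrix::rowSums(m^2)) / ncol(m)
  v <- pmax(ex2 - mu^2, 0) * ncol(m) / max(ncol(m) - 1, 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  nb <- max(1L, min(nBins, nrow(m)))
  br <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = nb + 1)))
  bin <- cut(mu, breaks = br, include.lowest = TRUE)
  z <- numeric(length(disp))
  for (b in levels(bin)) {
    i <- which(bin == b)
    mb <- mean(disp[i])
    sb <- stats::sd(disp[i])
    z[i] <- if (length(i) > 1 && isTRUE(sb > 0)) (disp[i] - mb) / sb
            else disp[i] - mb
  }
  z
}

#' TF-IDF normalization for peak-count matrices
#'
#' Entry \eqn{(f, c)} becomes \eqn{TF(f,c) \cdot IDF(f)} with
#' \eqn{TF(f,c) = x_{fc} / \sum_f x_{fc}} (column-stochastic term
#' frequency) and \eqn{IDF(f) = \log(1 + n / (1 + n_{open}(f)))} where
#' \eqn{n_{open}(f)} counts the cells in which feature \eqn{f} is nonzero.
#' The pseudocount keeps IDF finite for features open in no cell.
#'
#' @param view An [OmicsView-class] of nonnegative counts.
#' @return The normalized view; all entries finite and nonnegative.
#' @export
tfidfTransform <- function(view) {
  m <- view@matrix
  n <- ncol(m)
  cs <- Matrix::colSums(m)
  if (any(cs == 0)) {
    bad <- colnames(m)[which(cs == 0)[1L]]
    stop("cell '", bad, "' has zero total count; cannot compute TF")
  }
  nOpen <- Matrix::rowSums(m > 0)
  idf <- log(1 + n / (1 + nOpen))
  tf <- m %*% Matrix::Diagonal(x = 1 / cs)
  out <- Matrix::Diagonal(x = idf) %*% tf
  dimnames(out) <- dimnames(m)
  view@matrix <- .maybeSparsify(out)
  view@isSimplex <- FALSE
  view
}

#' Centered log-ratio normalization
#'
#' For compositional protein-tag (ADT) counts: per cell,
#' \eqn{x_i \mapsto \log(1 + x_i) - \mathrm{mean}_f \log(1 + x_f)}. The
#' pseudocount of 1 keeps the transform defined on the zeros present in raw
#' ADT counts. Each output column has mean zero.
#'
#' @param view An [OmicsView-class] of nonnegative counts.
#' @return The transformed view (dense; CLR output is signed).
#' @export
clrTransform <- function(view) {
  m <- log1p(as.matrix(view@matrix))
  m <- sweep(m, 2, colMeans(m))
  view@matrix <- m
  view@isSimplex <- FALSE
  view
}

#' Project columns onto the probability simplex
#'
#' Divides every column by its sum so the view becomes a collection of
#' discrete probability distributions over features, the form the
#' factorization consumes. Signed input (e.g. CLR output) is first shifted
#' by its per-column minimum to restore nonnegativity; a message records
#' the shift.
#'
#' @param view An [OmicsView-class].
#' @return The view with `isSimplex = TRUE`.
#' @export
toSimplex <- function(view) {
  m <- view@matrix
  mins <- apply(as.matrix(m), 2, min)
  if (any(mins < 0)) {
    message("shifting ", sum(mins < 0), " column(s) of '", view@name,
            "' by their minimum before simplex projection")
    m <- sweep(as.matrix(m), 2, pmin(mins, 0))
  }
  cs <- Matrix::colSums(m)
  if (any(cs == 0)) {
    bad <- colnames(m)[which(cs == 0)[1L]]
    stop("cell '", bad, "' has zero total; cannot project onto the simplex")
  }
  m <- m %*% Matrix::Diagonal(x = 1 / cs)
  dimnames(m) <- dimnames(view@matrix)
  view@matrix <- .maybeSparsify(m)
  view@isSimplex <- TRUE
  view
}

#' Run the standard per-modality preprocessing recipes
#'
#' Applies, per view, the recipe its modality calls for and finishes with
#' the simplex projection feeding the factorization:
#' \itemize{
#'   \item RNA-like: total-count normalization (target 10000), log1p,
#'     selection of the top `nTopRNA` variable genes, simplex projection.
#'   \item ATAC-like: either the same lognorm route or TF-IDF
#'     (`atacMethod = "tfidf"`), then top-`nTopATAC` peak selection and
#'     simplex projection.
#'   \item ADT-like: CLR, then simplex projection (no feature selection).
#' }
#' Views whose names are not recognized fall back to the RNA recipe.
#'
#' @param dataset A [MultiOmicsDataset-class] of raw counts.
#' @param nTopRNA,nTopATAC Number of variable features kept per modality
#'   (capped at the number of available features).
#' @param atacMethod `"lognorm"` or `"tfidf"`.
#' @param targetSum Total for the count normalization step.
#' @return The preprocessed dataset, every view on the simplex.
#' @export
preprocessDataset <- function(dataset, nTopRNA = 2500, nTopATAC = 5000,
                              atacMethod = c("lognorm", "tfidf"),
                              targetSum = 10000) {
  atacMethod <- match.arg(atacMethod)
  for (nm in viewNames(dataset)) {
    v <- getView(dataset, nm)
    kind <- .modalityKind(nm)
    if (kind == "adt") {
      v <- toSimplex(clrTransform(v))
    } else if (kind == "atac") {
      v <- if (atacMethod == "tfidf") tfidfTransform(v)
           else logTransform(normalizeTotal(v, targetSum))
      v <- selectHVG(v, min(nTopATAC, nrow(v@matrix)))
      v <- toSimplex(v)
    } else {
      v <- logTransform(normalizeTotal(v, targetSum))
      v <- selectHVG(v, min(nTopRNA, nrow(v@matrix)))
      v <- toSimplex(v)
    }
    dataset@views[[nm]] <- v
  }
  methods::validObject(dataset)
  dataset
}

.modalityKind <- function(name) {
  n <- tolower(name)
  if (grepl("adt|protein|cite", n)) return("adt")
  if (grepl("atac|peak|access", n)) return("atac")
  "rna"
}
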