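#' @import methods
#' @importClassesFrom Matrix Matrix
#' @importFrom Matrix Matrix sparseMatrix colSums rowSums t readMM writeMM
NULL

setClassUnion("matrixOrSparse", c("matrix", "Matrix"))

#' A single-modality view of a paired multi-omics dataset
#'
#' Holds one nonnegative features-by-cells matrix together with its modality
#' label. Feature and cell identifiers are carried as the matrix dimnames.
#' Matrices are stored in the features-by-cells orientation; readers that
#' encounter cells-by-features input transpose it and say so.
#'
#' @slot name Modality label, e.g. `"rna"`, `"atac"`, `"adt"`.
#' @slot matrix Nonnegative numeric matrix (dense `matrix` or a
#'   `Matrix` sparse matrix), features in rows, cells in columns, with
#'   unique rownames (feature ids) and colnames (cell ids).
#' @slot isSimplex Logical; `TRUE` once every column has been normalized to
#'   sum to 1 (a discrete probability distribution over features).
#'
#' @seealso [OmicsView()] for the user-facing constructor.
#' @export
setClass("OmicsView",
         representation(name = "character",
                        matrix = "matrixOrSparse",
                        isSimplex = "logical"))

# Class validity enforces structure (dimnames, unique ids, finiteness,
# simplex-flag consistency). Sign is checked by validateDataset() instead:
# intermediate transforms (CLR) legitimately hold signed values.
setValidity("OmicsView", function(object) {
  violations <- .viewViolations(object, checkSign = FALSE)
  if (length(violations) == 0L) TRUE else violations
})

#' Paired multi-omics dataset
#'
#' An ordered collection of [OmicsView-class] objects sharing the same cells
#' in the same order (the paired-data contract), with an optional per-cell
#' label vector used by the evaluation metrics.
#'
#' @slot views Named list of [OmicsView-class] objects.
#' @slot labels Factor of cell labels (length = number of cells) or a
#'   zero-length factor when no annotation is available.
#'
#' @export
setClass("MultiOmicsDataset",
         representation(views = "list", labels = "factor"))

setValidity("MultiOmicsDataset", function(object) {
  violations <- .datasetViolations(object, checkSign = FALSE)
  if (length(violations) == 0L) TRUE else violations
})

#' Fitted factor model
#'
#' Result of the optimal-transport factorization (or of the integrative NMF
#' baseline): per-modality dictionaries \eqn{H^{(p)}} (features x k, columns
#' on the probability simplex), a shared embedding \eqn{W} (k x cells,
#' columns on the simplex), the configuration used, and the per-outer-
#' iteration loss trace.
#'
#' @slot dictionaries Named list of features-by-k nonnegative matrices.
#' @slot embedding k-by-cells nonnegative matrix, columns summing to 1.
#' @slot k Number of latent dimensions.
#' @slot config List snapshot of the fitting configuration.
#' @slot lossTrace Numeric vector of loss values, one per outer iteration.
#' @slot simplex Logical; `FALSE` for models (such as the NMF baseline)
#'   whose columns are not constrained to the simplex.
#'
#' @export
setClass("FactorModel",
         representation(dictionaries = "list", embedding = "matrix",
                        k = "integer", config = "list",
                        lossTrace = "numeric", simplex = "logical"),
         prototype(simplex = TRUE))

setValidity("FactorModel", function(object) {
  msg <- character()
  k <- object@k
  if (ncol(object@embedding) > 0 && nrow(object@embedding) != k)
    msg <- c(msg, "embedding must have k rows")
  for (nm in names(object@dictionaries)) {
    H <- object@dictionaries[[nm]]
    if (ncol(H) != k)
      msg <- c(msg, sprintf("dictionary '%s' must have k columns", nm))
    if (any(H < 0))
      msg <- c(msg, sprintf("dictionary '%s' has negative entries", nm))
    if (object@simplex && any(abs(colSums(H) - 1) > 1e-6))
      msg <- c(msg, sprintf("dictionary '%s' columns must sum to 1", nm))
  }
  if (any(object@embedding < 0))
    msg <- c(msg, "embedding has negative entries")
  if (object@simplex && ncol(object@embedding) > 0 &&
      any(abs(colSums(object@embedding) - 1) > 1e-6))
    msg <- c(msg, "embedding columns must sum to 1")
  if (length(msg) == 0L) TRUE else msg
})

#' Optimal-transport context for one modality
#'
#' Bundles the feature-by-feature ground cost with the entropic
#' regularization strength. The cost is symmetric with zero diagonal and
#' entries in \[0, 2\] (cosine distances of nonnegative profiles lie in
#' \[0, 1\]).
#'
#' @slot cost Symmetric nonnegative cost matrix with zero diagonal.
#' @slot eps Positive entropic regularization parameter.
#' @slot modality Modality label the cost was derived from.
#'
#' @export
setClass("OTContext",
         representation(cost = "matrix", eps = "numeric",
                        modality = "character"))

setValidity("OTContext", function(object) {
  msg <- character()
  C <- object@cost
  if (nrow(C) != ncol(C)) msg <- c(msg, "cost must be square")
  if (any(!is.finite(C))) msg <- c(msg, "cost has non-finite entries")
  else {
    if (max(abs(diag(C))) > 1e-9) msg <- c(msg, "cost diagonal must be zero")
    if (max(abs(C - t(C))) > 1e-9) msg <- c(msg, "cost must be symmetric")
    if (min(C) < -1e-12 || max(C) > 2 + 1e-9)
      msg <- c(msg, "cost entries must lie in [0, 2]")
  }
  if (length(object@eps) != 1L || object@eps <= 0)
    msg <- c(msg, "eps must be a single positive number")
  if (length(msg) == 0L) TRUE else msg
})
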