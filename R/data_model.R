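#' Construct an OmicsView
#'
#' @param name Modality label (e.g. `"rna"`).
#' @param matrix Nonnegative features-by-cells matrix (dense or sparse) with
#'   rownames (feature ids) and colnames (cell ids). A matrix flagged as
#'   cells-by-features via `transpose = TRUE` is transposed on the way in.
#' @param isSimplex Set `TRUE` if every column already sums to 1.
#' @param transpose If `TRUE`, `matrix` is cells-by-features and is
#'   transposed to the internal features-by-cells orientation (a message is
#'   emitted so the transposition is on record).
#' @return An [OmicsView-class] object.
#' @examples
#' m <- matrix(rpois(12, 3), 4, 3,
#'             dimnames = list(paste0("g", 1:4), paste0("c", 1:3)))
#' v <- OmicsView("rna", m)
#' @export
OmicsView <- function(name, matrix, isSimplex = FALSE, transpose = FALSE) {
  if (transpose) {
    message("transposing cells-by-features input to features-by-cells for '",
            name, "'")
    matrix <- Matrix::t(matrix)
  }
  matrix <- .maybeSparsify(matrix)
  methods::new("OmicsView", name = name, matrix = matrix,
               isSimplex = isSimplex)
}

# Store sparsely when density < 0.5, densely otherwise. Operations accept
# both representations and give identical results up to tiny rounding.
.maybeSparsify <- function(m) {
  if (methods::is(m, "Matrix")) {
    dens <- Matrix::nnzero(m) / prod(dim(m))
    if (dens >= 0.5) return(as.matrix(m))
    return(methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix"))
  }
  dens <- sum(m != 0) / prod(dim(m))
  if (prod(dim(m)) > 0 && dens < 0.5)
    return(methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"))
  m
}

.viewViolations <- function(view, checkSign = TRUE) {
  msg <- character()
  m <- view@matrix
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, sprintf("view '%s': feature and cell ids (dimnames) required",
                          view@name))
  vals <- if (methods::is(m, "sparseMatrix")) m@x else as.vector(m)
  if (length(vals) && any(!is.finite(vals))) {
    idx <- which(!is.finite(vals))[1L]
    msg <- c(msg, sprintf("view '%s': non-finite entry (stored value %d)",
                          view@name, idx))
  } else if (checkSign && length(vals) && any(vals < 0)) {
    idx <- which(vals < 0)[1L]
    msg <- c(msg, sprintf("view '%s': negative entry (stored value %d)",
                          view@name, idx))
  }
  if (!is.null(rownames(m)) && anyDuplicated(rownames(m)))
    msg <- c(msg, sprintf("view '%s': duplicated feature ids (first: '%s')",
                          view@name, rownames(m)[anyDuplicated(rownames(m))]))
  if (!is.null(colnames(m)) && anyDuplicated(colnames(m)))
    msg <- c(msg, sprintf("view '%s': duplicated cell ids (first: '%s')",
                          view@name, colnames(m)[anyDuplicated(colnames(m))]))
  if (view@isSimplex && ncol(m) > 0) {
    cs <- Matrix::colSums(m)
    bad <- which(abs(cs - 1) > 1e-6)
    if (length(bad))
      msg <- c(msg, sprintf(
        "view '%s': simplex flag set but column %d sums to %.8f",
        view@name, bad[1L], cs[bad[1L]]))
  }
  msg
}

.datasetViolations <- function(object, checkSign = TRUE) {
  msg <- character()
  if (length(object@views) < 1L) {
    return("dataset must contain at least one view")
  }
  if (is.null(names(object@views)) || anyDuplicated(names(object@views)))
    msg <- c(msg, "views must be uniquely named")
  for (v in object@views) {
    if (!methods::is(v, "OmicsView")) {
      return("all views must be OmicsView objects")
    }
    msg <- c(msg, .viewViolations(v, checkSign = checkSign))
  }
  ref <- colnames(object@views[[1L]]@matrix)
  for (v in object@views[-1L]) {
    ids <- colnames(v@matrix)
    if (is.null(ids) || length(ids) != length(ref) || any(ids != ref)) {
      if (!is.null(ids) && setequal(ids, ref))
        msg <- c(msg, sprintf(
          "view '%s': cell order mismatch with view '%s'",
          v@name, object@views[[1L]]@name))
      else
        msg <- c(msg, sprintf(
          "view '%s': cell ids differ from view '%s'",
          v@name, object@views[[1L]]@name))
    }
  }
  if (length(object@labels) > 0 && length(object@labels) != length(ref))
    msg <- c(msg, "labels length must equal the number of cells")
  msg
}

#' Construct a MultiOmicsDataset
#'
#' @param views List of [OmicsView-class] objects (or a single view). Names
#'   default to the views' modality labels.
#' @param labels Optional per-cell annotation (factor or character), used by
#'   the evaluation metrics.
#' @return A [MultiOmicsDataset-class] object.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3), c("c1", "c2")))
#' ds <- MultiOmicsDataset(list(OmicsView("rna", m)))
#' @export
MultiOmicsDataset <- function(views, labels = factor()) {
  if (methods::is(views, "OmicsView")) views <- list(views)
  if (is.null(names(views)))
    names(views) <- vapply(views, function(v) v@name, character(1))
  methods::new("MultiOmicsDataset", views = views,
               labels = as.factor(labels))
}

#' List the invariant violations of a dataset
#'
#' Checks nonnegativity, finiteness, unique feature/cell ids, simplex
#' column sums where flagged, and the paired-cells contract across views.
#' Unlike the class validity hook this never throws: it reports.
#'
#' @param dataset A [MultiOmicsDataset-class] object.
#' @return Character vector of human-readable violations; empty when all
#'   invariants hold.
#' @export
validateDataset <- function(dataset) {
  .datasetViolations(dataset)
}

#' @rdname viewNames
#' @export
setGeneric("viewNames", function(x) standardGeneric("viewNames"))

#' Accessors for multi-omics datasets and factor models
#'
#' `viewNames()` lists the modalities; `getView()` extracts one
#' [OmicsView-class]; `cellIDs()` and `featureIDs()` return identifier
#' vectors; `cellLabels()` the annotation; `nCells()` the number of shared
#' cells. For [FactorModel-class]: `dictionaries()`, `embedding()`,
#' `latentDim()` and `lossTrace()`.
#'
#' @param x A [MultiOmicsDataset-class], [OmicsView-class] or
#'   [FactorModel-class] object as appropriate.
#' @param name Modality name (for `getView` / `featureIDs` on a dataset).
#' @return The requested component.
#' @name viewNames
#' @aliases viewNames,MultiOmicsDataset-method
#' @export
setMethod("viewNames", "MultiOmicsDataset", function(x) names(x@views))

#' @rdname viewNames
#' @export
setGeneric("getView", function(x, name) standardGeneric("getView"))

#' @rdname viewNames
#' @export
setMethod("getView", "MultiOmicsDataset", function(x, name) {
  if (!name %in% names(x@views))
    stop("no view named '", name, "'")
  x@views[[name]]
})

#' @rdname viewNames
#' @export
setGeneric("cellIDs", function(x) standardGeneric("cellIDs"))

#' @rdname viewNames
#' @export
setMethod("cellIDs", "MultiOmicsDataset",
          function(x) colnames(x@views[[1L]]@matrix))

#' @rdname viewNames
#' @export
setMethod("cellIDs", "OmicsView", function(x) colnames(x@matrix))

#' @rdname viewNames
#' @export
setGeneric("featureIDs", function(x, name) standardGeneric("featureIDs"))

#' @rdname viewNames
#' @export
setMethod("featureIDs", "OmicsView", function(x, name) rownames(x@matrix))

#' @rdname viewNames
#' @export
setMethod("featureIDs", "MultiOmicsDataset",
          function(x, name) rownames(getView(x, name)@matrix))

#' @rdname viewNames
#' @export
setGeneric("cellLabels", function(x) standardGeneric("cellLabels"))

#' @rdname viewNames
#' @export
setMethod("cellLabels", "MultiOmicsDataset", function(x) x@labels)

#' @rdname viewNames
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname viewNames
#' @export
setMethod("nCells", "MultiOmicsDataset",
          function(x) ncol(x@views[[1L]]@matrix))

#' @rdname viewNames
#' @export
setGeneric("viewMatrix", function(x) standardGeneric("viewMatrix"))

#' @rdname viewNames
#' @export
setMethod("viewMatrix", "OmicsView", function(x) x@matrix)

#' @rdname viewNames
#' @export
setGeneric("dictionaries", function(x) standardGeneric("dictionaries"))

#' @rdname viewNames
#' @export
setMethod("dictionaries", "FactorModel", function(x) x@dictionaries)

#' @rdname viewNames
#' @export
setGeneric("embedding", function(x) standardGeneric("embedding"))

#' @rdname viewNames
#' @export
setMethod("embedding", "FactorModel", function(x) x@embedding)

#' @rdname viewNames
#' @export
setGeneric("latentDim", function(x) standardGeneric("latentDim"))

#' @rdname viewNames
#' @export
setMethod("latentDim", "FactorModel", function(x) x@k)

#' @rdname viewNames
#' @export
setGeneric("lossTrace", function(x) standardGeneric("lossTrace"))

#' @rdname viewNames
#' @export
setMethod("lossTrace", "FactorModel", function(x) x@lossTrace)

setMethod("show", "OmicsView", function(object) {
  cat(sprintf("OmicsView '%s': %d features x %d cells (%s%s)\n",
              object@name, nrow(object@matrix), ncol(object@matrix),
              if (methods::is(object@matrix, "Matrix")) "sparse" else "dense",
              if (object@isSimplex) ", simplex" else ""))
})

setMethod("show", "MultiOmicsDataset", function(object) {
  cat(sprintf("MultiOmicsDataset: %d view(s), %d cells\n",
              length(object@views), nCells(object)))
  for (v in object@views)
    cat(sprintf("  %-6s %6d features (%s)\n", v@name, nrow(v@matrix),
                if (v@isSimplex) "simplex" else "raw"))
  if (length(object@labels))
    cat("  labels:", paste(levels(object@labels), collapse = ", "), "\n")
})

setMethod("show", "FactorModel", function(object) {
  cat(sprintf("FactorModel: k = %d, %d cells, %d modalit%s\n", object@k,
              ncol(object@embedding), length(object@dictionaries),
              if (length(object@dictionaries) == 1) "y" else "ies"))
  if (length(object@lossTrace))
    cat(sprintf("  final loss %.6g after %d outer iteration(s)\n",
                utils::tail(object@lossTrace, 1), length(object@lossTrace)))
})

# Replace the matrices of a dataset's views, preserving structure.
.replaceViewMatrix <- function(dataset, name, m, isSimplex = NULL) {
  v <- dataset@views[[name]]
  v@matrix <- .maybeSparsify(m)
  if (!is.null(isSimplex)) v@isSimplex <- isSimplex
  dataset@views[[name]] <- v
  methods::validObject(v)
  dataset
}

# Subset all views of a dataset to the given cell indices (paired contract).
.subsetCells <- function(dataset, idx) {
  for (nm in names(dataset@views)) {
    v <- dataset@views[[nm]]
    v@matrix <- v@matrix[, idx, drop = FALSE]
    dataset@views[[nm]] <- v
  }
  if (length(dataset@labels))
    dataset@labels <- droplevels(dataset@labels[idx])
  dataset
}
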