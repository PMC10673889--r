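#' Read one modality from Matrix Market + feature/barcode files
#'
#' Standard triplet layout: a Matrix Market coordinate file (1-based
#' indices, features in rows) plus plain-text feature and barcode lists.
#' Counts are preserved exactly.
#'
#' @param pathMatrix Path to the `.mtx` file.
#' @param pathFeatures,pathBarcodes One id per line (first column of a
#'   TSV is used if there are several).
#' @param name Modality label for the resulting view.
#' @return An [OmicsView-class].
#' @export
readMTXView <- function(pathMatrix, pathFeatures, pathBarcodes,
                        name = "rna") {
  m <- Matrix::readMM(pathMatrix)
  feats <- .readIdColumn(pathFeatures)
  cells <- .readIdColumn(pathBarcodes)
  if (nrow(m) != length(feats))
    stop("feature count mismatch: matrix has ", nrow(m), " rows but '",
         pathFeatures, "' lists ", length(feats))
  if (ncol(m) != length(cells))
    stop("barcode count mismatch: matrix has ", ncol(m), " columns but '",
         pathBarcodes, "' lists ", length(cells))
  dimnames(m) <- list(feats, cells)
  OmicsView(name, methods::as(m, "CsparseMatrix"))
}

.readIdColumn <- function(path) {
  x <- readLines(path)
  vapply(strsplit(x, "\t", fixed = TRUE), `[`, character(1), 1)
}

#' Read one modality from a dense CSV
#'
#' Header row holds the cell ids; the first column holds feature ids.
#'
#' @param path CSV path.
#' @param name Modality label.
#' @param transpose Set `TRUE` if the file is cells-by-features.
#' @return An [OmicsView-class].
#' @export
readCSVView <- function(path, name = "rna", transpose = FALSE) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  OmicsView(name, as.matrix(df), transpose = transpose)
}

# Full-precision Matrix Market writer (integer counts round-trip
# bit-identically; reals keep 17 significant digits).
.writeMTX <- function(m, path) {
  m <- methods::as(Matrix::Matrix(m, sparse = TRUE), "TsparseMatrix")
  vals <- m@x
  isInt <- all(vals == round(vals)) && all(abs(vals) < 2^31)
  field <- if (isInt) "integer" else "real"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("%%%%MatrixMarket matrix coordinate %s general",
                       field),
               sprintf("%d %d %d", nrow(m), ncol(m), length(vals))), con)
  if (length(vals)) {
    lines <- if (isInt)
      sprintf("%d %d %d", m@i + 1L, m@j + 1L, as.integer(vals))
    else sprintf("%d %d %.17g", m@i + 1L, m@j + 1L, vals)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write a dataset to a plain-text multimodal container
#'
#' One subdirectory per modality (`matrix.mtx`, `features.tsv`,
#' `barcodes.tsv`) plus `labels.tsv` when labels are present and a
#' `manifest.json` recording the schema version, view order and simplex
#' flags. Integer counts round-trip bit-identically; real values to
#' within 1e-12 relative.
#'
#' @param dataset A [MultiOmicsDataset-class].
#' @param dir Container directory (created, must not already contain a
#'   manifest unless `overwrite = TRUE`).
#' @param overwrite Allow writing over an existing container.
#' @return Invisibly, `dir`.
#' @export
writeDataset <- function(dataset, dir, overwrite = FALSE) {
  manifest <- file.path(dir, "manifest.json")
  if (file.exists(manifest) && !overwrite)
    stop("container already exists at '", dir,
         "'; use overwrite = TRUE to replace it")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in viewNames(dataset)) {
    v <- getView(dataset, nm)
    vd <- file.path(dir, nm)
    dir.create(vd, showWarnings = FALSE)
    .writeMTX(v@matrix, file.path(vd, "matrix.mtx"))
    writeLines(rownames(v@matrix), file.path(vd, "features.tsv"))
    writeLines(colnames(v@matrix), file.path(vd, "barcodes.tsv"))
  }
  if (length(cellLabels(dataset)))
    utils::write.table(
      data.frame(cell = cellIDs(dataset),
                 label = as.character(cellLabels(dataset))),
      file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  jsonlite::write_json(
    list(schema_version = "1.0",
         views = lapply(viewNames(dataset), function(nm)
           list(name = nm,
                isSimplex = getView(dataset, nm)@isSimplex))),
    manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a dataset from a plain-text multimodal container
#'
#' @param dir Directory written by [writeDataset()].
#' @return A [MultiOmicsDataset-class].
#' @export
readDataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  views <- lapply(manifest$views, function(vm) {
    vd <- file.path(dir, vm$name)
    v <- readMTXView(file.path(vd, "matrix.mtx"),
                     file.path(vd, "features.tsv"),
                     file.path(vd, "barcodes.tsv"), name = vm$name)
    v@isSimplex <- isTRUE(vm$isSimplex)
    methods::validObject(v)
    v
  })
  names(views) <- vapply(manifest$views, `[[`, character(1), "name")
  labels <- factor()
  lp <- file.path(dir, "labels.tsv")
  if (file.exists(lp)) {
    lab <- utils::read.delim(lp)
    labels <- factor(lab$label)
  }
  MultiOmicsDataset(views, labels = labels)
}

#' Write a fitted model to a plain-text directory
#'
#' `W.csv`, one `H_<view>.csv` per modality, `loss_trace.csv` and
#' `config.json`.
#'
#' @param model A [FactorModel-class].
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
writeFactorModel <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(embedding(model), file.path(dir, "W.csv"))
  for (nm in names(dictionaries(model)))
    utils::write.csv(dictionaries(model)[[nm]],
                     file.path(dir, paste0("H_", nm, ".csv")))
  utils::write.csv(data.frame(iteration = seq_along(lossTrace(model)),
                              loss = lossTrace(model)),
                   file.path(dir, "loss_trace.csv"), row.names = FALSE)
  cfg <- model@config
  cfg$k <- model@k
  cfg$simplex <- model@simplex
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read a fitted model from a directory written by [writeFactorModel()]
#'
#' @param dir Model directory.
#' @return A [FactorModel-class].
#' @export
readFactorModel <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  W <- as.matrix(utils::read.csv(file.path(dir, "W.csv"), row.names = 1,
                                 check.names = FALSE))
  hFiles <- list.files(dir, pattern = "^H_.*\\.csv$", full.names = TRUE)
  dicts <- lapply(hFiles, function(f)
    as.matrix(utils::read.csv(f, row.names = 1, check.names = FALSE)))
  names(dicts) <- sub("^H_(.*)\\.csv$", "\\1", basename(hFiles))
  trace <- utils::read.csv(file.path(dir, "loss_trace.csv"))$loss
  simplex <- isTRUE(cfg$simplex)
  cfg$simplex <- NULL
  k <- as.integer(cfg$k)
  methods::new("FactorModel", dictionaries = dicts, embedding = W,
               k = k, config = as.list(cfg),
               lossTrace = as.numeric(trace), simplex = simplex)
}
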