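#' Row-normalize a loading matrix
#'
#' Divides each nonzero row of a dictionary by its sum, making features
#' comparable before ranking them within factors. Zero rows are left zero,
#' with a warning.
#'
#' @param H Nonnegative features-by-factors matrix.
#' @return The row-normalized matrix (nonzero rows sum to 1).
#' @export
normalizeLoadingRows <- function(H) {
  H <- as.matrix(H)
  rs <- rowSums(H)
  zero <- rs == 0
  if (any(zero))
    warning(sum(zero), " zero loading row(s) left unnormalized")
  rs[zero] <- 1
  H / rs
}

#' Top features of a factor
#'
#' Features sorted by descending weight in the factor's column of the
#' (typically row-normalized) loading matrix; ties are broken by feature
#' index. Conventional sizes are 150 for gene-like and 100 for peak-like
#' loadings.
#'
#' @param H Features-by-factors matrix with rownames.
#' @param factor Column index or name.
#' @param nTop Number of features to return (must not exceed the number
#'   of features).
#' @return Character vector of feature ids, best first.
#' @export
topFeatures <- function(H, factor, nTop = 150) {
  H <- as.matrix(H)
  if (nTop > nrow(H))
    stop("nTop (", nTop, ") exceeds the number of features (", nrow(H), ")")
  w <- H[, factor]
  ord <- order(-w, seq_along(w))
  rownames(H)[ord[seq_len(nTop)]]
}

#' Enrichment background
#'
#' The union over all factors of each factor's top features — the
#' background set handed to downstream enrichment tools alongside the
#' per-factor top lists.
#'
#' @param H Features-by-factors matrix with rownames.
#' @param nTop Top-list size per factor.
#' @return Sorted character vector of feature ids.
#' @export
enrichmentBackground <- function(H, nTop = 100) {
  sets <- lapply(seq_len(ncol(as.matrix(H))), function(j)
    topFeatures(H, j, nTop))
  sort(unique(unlist(sets)))
}

# "chr:start-end" (1-based, inclusive) -> BED3 (0-based, half-open).
.peaksToBed <- function(ids) {
  m <- regmatches(ids, regexec("^([^:]+):([0-9]+)-([0-9]+)$", ids))
  bad <- ids[vapply(m, length, integer(1)) != 4L]
  if (length(bad))
    stop("unparsable peak id(s): ", paste(utils::head(bad, 5),
                                          collapse = ", "))
  data.frame(chrom = vapply(m, `[`, character(1), 2),
             start = as.integer(vapply(m, `[`, character(1), 3)) - 1L,
             end = as.integer(vapply(m, `[`, character(1), 4)))
}

.writeBed <- function(bed, path) {
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Export interpretation inputs for a fitted model
#'
#' Writes, per modality, the files downstream enrichment tools consume:
#' \itemize{
#'   \item gene-like dictionaries: one ranked gene list per factor
#'     (`genes_<view>_factor<i>.txt`, one id per line; ranked for
#'     inspection — enrichment tools typically treat the list as
#'     unordered);
#'   \item peak-like dictionaries: one BED3 file of top peaks per factor
#'     plus a background BED of the union of top peaks across factors.
#'     Peak ids must follow `chrom:start-end` (1-based inclusive),
#'     converted to 0-based half-open BED;
#'   \item protein-like dictionaries: one TSV of top proteins and weights
#'     per factor.
#' }
#' Rows of every dictionary are normalized to sum to 1 before ranking.
#' Downstream gene-set selection conventionally keeps terms with
#' Bonferroni-adjusted p-values below 0.05; the enrichment test itself is
#' out of scope here. Outputs are a pure function of the model: rerunning
#' the export reproduces identical files.
#'
#' @param model A [FactorModel-class].
#' @param outDir Output directory (created if needed).
#' @param nTopGenes,nTopPeaks,nTopProteins Top-list sizes (capped at the
#'   number of available features).
#' @return Invisibly, the vector of written file paths.
#' @export
exportInterpretation <- function(model, outDir, nTopGenes = 150,
                                 nTopPeaks = 100, nTopProteins = 20) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (nm in names(dictionaries(model))) {
    H <- normalizeLoadingRows(dictionaries(model)[[nm]])
    kind <- .modalityKind(nm)
    k <- ncol(H)
    if (kind == "atac") {
      nTop <- min(nTopPeaks, nrow(H))
      for (j in seq_len(k)) {
        p <- file.path(outDir, sprintf("peaks_%s_factor%d.bed", nm, j))
        .writeBed(.peaksToBed(topFeatures(H, j, nTop)), p)
        written <- c(written, p)
      }
      p <- file.path(outDir, sprintf("background_%s.bed", nm))
      .writeBed(.peaksToBed(enrichmentBackground(H, nTop)), p)
      written <- c(written, p)
    } else if (kind == "adt") {
      nTop <- min(nTopProteins, nrow(H))
      for (j in seq_len(k)) {
        ids <- topFeatures(H, j, nTop)
        p <- file.path(outDir, sprintf("proteins_%s_factor%d.tsv", nm, j))
        utils::write.table(data.frame(protein = ids, weight = H[ids, j]),
                           p, sep = "\t", quote = FALSE, row.names = FALSE)
        written <- c(written, p)
      }
    } else {
      nTop <- min(nTopGenes, nrow(H))
      for (j in seq_len(k)) {
        p <- file.path(outDir, sprintf("genes_%s_factor%d.txt", nm, j))
        writeLines(topFeatures(H, j, nTop), p)
        written <- c(written, p)
      }
    }
  }
  invisible(written)
}
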