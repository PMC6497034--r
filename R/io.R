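# Reading and writing the 10x-style Matrix Market triplet and the flat
# text formats used around it.

#' Write a count matrix as a 10x-style Matrix Market triplet
#'
#' Writes `matrix.mtx` (genes as rows), `genes.tsv`, `barcodes.tsv` and, if
#' cell metadata is present, `cells.tsv` (tab-separated colData with a
#' `barcode` column) to `dir`.
#'
#' @param x a `SingleCellExperiment`/`SummarizedExperiment` with a `counts`
#'   assay, or a genes x cells matrix.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCounts10x <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- .countsOf(x)
  Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(m) %||% character(0), file.path(dir, "genes.tsv"))
  writeLines(colnames(m) %||% character(0), file.path(dir, "barcodes.tsv"))
  if (is(x, "SummarizedExperiment") && ncol(colData(x)) > 0) {
    cd <- as.data.frame(colData(x))
    cd <- cbind(barcode = rownames(cd), cd)
    utils::write.table(cd, file.path(dir, "cells.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a 10x-style Matrix Market triplet
#'
#' Reads `matrix.mtx` + `genes.tsv` + `barcodes.tsv` (genes as rows) and, if
#' present, per-cell metadata from `cells.tsv`, validating the header and
#' the dimension agreement between the matrix and the id files.
#'
#' @param dir directory holding the triplet.
#' @return a `SingleCellExperiment` with a sparse `counts` assay.
#' @export
readCounts10x <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) stop("no matrix.mtx in ", dir)
  hdr <- readLines(mtx, n = 1L)
  if (!startsWith(hdr, "%%MatrixMarket matrix coordinate"))
    stop("malformed Matrix Market header at line 1 of ", mtx)
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  genes <- readLines(file.path(dir, "genes.tsv"))
  genes <- vapply(strsplit(genes, "\t"), `[[`, character(1), 1L)
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  if (length(genes) != nrow(m))
    stop(sprintf("genes.tsv has %d ids but matrix.mtx declares %d rows",
                 length(genes), nrow(m)))
  if (length(barcodes) != ncol(m))
    stop(sprintf("barcodes.tsv has %d ids but matrix.mtx declares %d columns",
                 length(barcodes), ncol(m)))
  dimnames(m) <- list(genes, barcodes)
  cd <- DataFrame(row.names = barcodes)
  cells_f <- file.path(dir, "cells.tsv")
  if (file.exists(cells_f)) {
    tab <- utils::read.table(cells_f, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    if (!identical(tab$barcode, barcodes))
      stop("cells.tsv barcodes disagree with barcodes.tsv")
    cd <- DataFrame(tab[, setdiff(colnames(tab), "barcode"), drop = FALSE],
                    row.names = barcodes)
  }
  SingleCellExperiment(assays = list(counts = m), colData = cd)
}

#' Read / write an embedding as TSV
#'
#' Tab-separated table with a `cell` column followed by coordinate columns.
#'
#' @param x cells x d coordinate matrix with rownames.
#' @param path file path.
#' @return `readEmbeddingTSV` returns the coordinate matrix.
#' @export
writeEmbeddingTSV <- function(x, path) {
  df <- data.frame(cell = rownames(x), as.data.frame(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEmbeddingTSV
#' @export
readEmbeddingTSV <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Read / write gene sets as plain text
#'
#' `readGeneSets` accepts one-gene-per-line files (one file per set) or a
#' GMT-style file (set name, description, then genes, tab-separated).
#'
#' @param paths character vector of one-gene-per-line files (named by set)
#'   or a single GMT file when `gmt = TRUE`.
#' @param gmt whether `paths` is one GMT-style file.
#' @param universe optional universe passed to [geneSetCollection()].
#' @return a [GeneSetCollection-class].
#' @export
readGeneSets <- function(paths, gmt = FALSE, universe = NULL) {
  if (gmt) {
    rows <- strsplit(readLines(paths[[1L]]), "\t")
    sets <- lapply(rows, function(r) r[-c(1L, 2L)])
    names(sets) <- vapply(rows, `[[`, character(1), 1L)
  } else {
    sets <- lapply(paths, readLines)
    names(sets) <- names(paths) %||%
      sub("\\.[^.]*$", "", basename(unlist(paths)))
  }
  geneSetCollection(sets, universe)
}

#' @rdname readGeneSets
#' @param sets a [GeneSetCollection-class] to write.
#' @param path output GMT-style file.
#' @export
writeGeneSetsGMT <- function(sets, path) {
  lines <- vapply(names(sets@sets), function(nm)
    paste(c(nm, "na", sets@sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
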