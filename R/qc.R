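# Cell and gene quality filtration rules.

.countsOf <- function(x) {
  if (is(x, "SummarizedExperiment")) assay(x, "counts") else x
}

#' Detected-gene mask
#'
#' A gene counts as "detected" in a dataset when it is expressed at
#' UMI >= 1 in at least `min_cells_per_gene` individual cells of that
#' dataset. All per-cell QC statistics are computed over detected genes
#' only, so the mask is applied before [computeCellQC()].
#'
#' @param counts genes x cells count matrix (sparse or dense) or a
#'   `SummarizedExperiment` with a `counts` assay.
#' @param min_cells_per_gene minimum number of cells with UMI >= 1
#'   (default 30).
#' @return named logical vector over genes; `TRUE` = detected.
#' @examples
#' m <- matrix(c(1, 0, 0, 2, 3, 0), 2, dimnames = list(c("A", "B"), NULL))
#' detectedGeneMask(m, min_cells_per_gene = 2)
#' @export
detectedGeneMask <- function(counts, min_cells_per_gene = 30) {
  if (min_cells_per_gene < 1) stop("'min_cells_per_gene' must be >= 1")
  m <- .countsOf(counts)
  if (ncol(m) == 0L || nrow(m) == 0L)
    return(setNames(logical(nrow(m)), rownames(m)))
  setNames(Matrix::rowSums(m >= 1) >= min_cells_per_gene, rownames(m))
}

#' Per-cell QC statistics
#'
#' Computes, per cell, the number of detected genes (genes with UMI >= 1 in
#' the cell), the total UMI count, and the mitochondrial fraction.
#' Mitochondrial genes are recognised by a case-insensitive id prefix.
#' The mitochondrial fraction is the mitochondrial share of the cell's UMIs
#' by default (`mito_mode = "umi"`), or the mitochondrial share of its
#' detected genes (`mito_mode = "genes"`); both conventions appear in
#' published filtration rules. All-zero cells have fraction 0 by convention.
#' The detected-gene mask ([detectedGeneMask()]) is expected to have been
#' applied already.
#'
#' @param counts genes x cells matrix or `SummarizedExperiment`, restricted
#'   to detected genes.
#' @param mito_prefix gene-id prefix identifying mitochondrial genes.
#' @param mito_mode `"umi"` (UMI share, default) or `"genes"` (detected-gene
#'   share).
#' @return a [S4Vectors::DataFrame] with columns `detected_genes`,
#'   `total_umi`, `mito_fraction`, rownames = cell ids.
#' @export
computeCellQC <- function(counts, mito_prefix = "MT-",
                          mito_mode = c("umi", "genes")) {
  mito_mode <- match.arg(mito_mode)
  m <- .countsOf(counts)
  mito <- startsWith(toupper(rownames(m) %||% character(nrow(m))),
                     toupper(mito_prefix))
  detected <- Matrix::colSums(m >= 1)
  total <- Matrix::colSums(m)
  if (mito_mode == "umi") {
    mito_num <- Matrix::colSums(m[mito, , drop = FALSE])
    denom <- total
  } else {
    mito_num <- Matrix::colSums(m[mito, , drop = FALSE] >= 1)
    denom <- detected
  }
  frac <- ifelse(denom > 0, mito_num / denom, 0)
  DataFrame(detected_genes = as.integer(detected),
            total_umi = as.numeric(total),
            mito_fraction = as.numeric(frac),
            row.names = colnames(m))
}

#' QC threshold set
#'
#' A cell is abnormal when its detected-gene number is below `min_genes`,
#' above `max_genes`, or its mitochondrial fraction exceeds `max_mito`.
#' `max_genes` and `max_mito` are dataset-specific; typical published
#' settings pair a common lower bound of 400 detected genes with
#' dataset-wise upper bounds of 2000--3500 genes and mito caps of 6--8\%.
#'
#' @param min_genes lower detected-gene bound (cells strictly below are
#'   removed).
#' @param max_genes upper detected-gene bound (cells strictly above are
#'   removed).
#' @param max_mito mitochondrial-fraction cap (cells strictly above are
#'   removed).
#' @param min_cells_per_gene detected-gene mask threshold carried alongside.
#' @return a named list of class `QCThresholds`.
#' @export
qcThresholds <- function(min_genes = 400, max_genes = 2000, max_mito = 0.08,
                         min_cells_per_gene = 30) {
  if (!(min_genes < max_genes))
    stop("'min_genes' must be smaller than 'max_genes'")
  if (max_mito <= 0 || max_mito > 1)
    stop("'max_mito' must lie in (0, 1]")
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 max_mito = max_mito,
                 min_cells_per_gene = min_cells_per_gene),
            class = "QCThresholds")
}

#' Filter cells on QC statistics
#'
#' Removes a cell iff `detected_genes < min_genes` OR
#' `detected_genes > max_genes` OR `mito_fraction > max_mito`; the order of
#' the criteria is irrelevant.
#'
#' @param qc per-cell QC table from [computeCellQC()].
#' @param thresholds a [qcThresholds()] list.
#' @return character vector of kept cell ids.
#' @export
filterCells <- function(qc, thresholds) {
  stopifnot(inherits(thresholds, "QCThresholds"))
  keep <- qc$detected_genes >= thresholds$min_genes &
    qc$detected_genes <= thresholds$max_genes &
    qc$mito_fraction <= thresholds$max_mito
  rownames(qc)[keep]
}

#' Flag hemoglobin-high (NRBC-like) clusters
#'
#' Scores every cell by its mean normalized expression over a hemoglobin
#' gene list, averages the score within clusters, and flags a cluster iff
#' its mean score lies more than `z_min` standard deviations above the
#' across-cluster mean of the score. Nucleated red blood cells express
#' massive amounts of hemoglobin genes (HBG1, HBM, ...) and segregate by
#' sample, so they are flagged and set aside before batch merging.
#'
#' Note the z-score uses the SD over all cluster means (including the
#' candidate), so with k clusters a single outlier can reach at most
#' \eqn{(k-1)/\sqrt{k}}; a `z_min` of 2 therefore needs 6 or more clusters.
#'
#' @param norm_expr genes x cells normalized matrix (see [logNormalize()]).
#' @param clusters cluster label per cell.
#' @param hb_genes hemoglobin gene ids (must intersect the matrix rows).
#' @param z_min flagging threshold in across-cluster SD units (default 2).
#' @return character vector of flagged cluster ids.
#' @export
flagHemoglobinClusters <- function(norm_expr, clusters, hb_genes,
                                   z_min = 2) {
  if (length(hb_genes) == 0L) stop("'hb_genes' must not be empty")
  m <- .countsOf(norm_expr)
  hb <- intersect(hb_genes, rownames(m))
  if (length(hb) == 0L) stop("none of 'hb_genes' found in the matrix")
  clusters <- as.character(clusters)
  if (length(clusters) != ncol(m))
    stop("'clusters' must have one label per cell")
  if (length(unique(clusters)) < 2L) stop("need at least 2 clusters")
  score <- Matrix::colMeans(m[hb, , drop = FALSE])
  cl_mean <- tapply(score, clusters, mean)
  s <- sd(cl_mean)
  if (is.na(s) || s == 0) return(character(0))
  z <- (cl_mean - mean(cl_mean)) / s
  names(z)[z > z_min]
}

#' Trajectory mitochondrial exclusion
#'
#' Within a trajectory cell subset, removes cells whose mitochondrial
#' fraction exceeds `max_mito` (default 2.5\%) before pseudotime inference;
#' cells at exactly the threshold are kept.
#'
#' @param qc per-cell QC table from [computeCellQC()], restricted to the
#'   trajectory subset.
#' @param max_mito mitochondrial-fraction cap (default 0.025).
#' @return character vector of kept cell ids.
#' @export
trajectoryMitoExclusion <- function(qc, max_mito = 0.025) {
  rownames(qc)[qc$mito_fraction <= max_mito]
}
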