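# Log-normalization, cluster marker detection, doublet-cluster flagging and
# reference-correlation annotation.

#' Log-normalize a UMI count matrix
#'
#' Per cell: `ln(1 + scale * count / total)`, the standard library-size
#' log-normalization. All-zero cells map to zeros.
#'
#' @param counts genes x cells count matrix (sparse or dense) or a
#'   `SummarizedExperiment` with a `counts` assay.
#' @param scale size factor target (default 1e4).
#' @return normalized matrix of the same shape (sparse if the input was).
#' @examples
#' logNormalize(matrix(c(5, 0, 5, 0), 2), scale = 10)
#' @export
logNormalize <- function(counts, scale = 1e4) {
  if (scale <= 0) stop("'scale' must be positive")
  m <- .countsOf(counts)
  tot <- Matrix::colSums(m)
  fac <- ifelse(tot > 0, scale / tot, 0)
  out <- m %*% Matrix::Diagonal(x = fac)
  out <- log1p(out)
  dimnames(out) <- dimnames(m)
  out
}

# Exact two-sided rank-sum p-value in the presence of ties, by dynamic
# programming over the distribution of the group-1 rank sum across all
# C(n, n1) assignments.  Ranks are doubled so tied (half-integer) average
# ranks become integers; subset counts stay below 2^53 for n <= 40.
.ranksumExactP <- function(x, in_group) {
  n <- length(x)
  n1 <- sum(in_group)
  r2 <- as.integer(round(2 * rank(x)))
  W2 <- sum(r2[in_group])
  maxs <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
  f <- matrix(0, n1 + 1L, maxs + 1L)
  f[1L, 1L] <- 1
  for (r in r2) {
    for (j in seq.int(n1, 1L)) {
      src <- f[j, seq_len(maxs - r + 1L)]
      tgt <- seq.int(r + 1L, maxs + 1L)
      f[j + 1L, tgt] <- f[j + 1L, tgt] + src
    }
  }
  cnt <- f[n1 + 1L, ]
  mu2 <- n1 * (n + 1)
  dev <- abs(seq.int(0L, maxs) - mu2)
  p <- sum(cnt[dev >= abs(W2 - mu2) - 1e-9]) / choose(n, n1)
  min(p, 1)
}

# Normal-approximation two-sided rank-sum p-values with tie correction and
# continuity correction, vectorized over the rows of a matrix.
.ranksumApproxP <- function(X, in_group) {
  n <- ncol(X)
  n1 <- sum(in_group)
  n2 <- n - n1
  R <- t(apply(X, 1L, rank))
  if (nrow(X) == 1L) R <- matrix(R, 1L)
  W <- rowSums(R[, in_group, drop = FALSE])
  tiecorr <- apply(X, 1L, function(v) {
    tt <- tabulate(match(v, unique(v)))
    sum(tt^3 - tt)
  })
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - tiecorr / (n * (n - 1)))
  d <- W - n1 * (n + 1) / 2
  z <- (d - sign(d) * 0.5) / sqrt(sigma2)
  p <- 2 * pnorm(-abs(z))
  p[sigma2 <= 0] <- 1
  pmin(p, 1)
}

# Dispatch: exact enumeration when both group sizes are small enough,
# normal approximation otherwise.
.ranksumP <- function(X, in_group, exact_max_n = 20) {
  n1 <- sum(in_group)
  n2 <- ncol(X) - n1
  if (max(n1, n2) <= exact_max_n)
    vapply(seq_len(nrow(X)),
           function(i) .ranksumExactP(X[i, ], in_group), numeric(1))
  else .ranksumApproxP(X, in_group)
}

#' Cluster-versus-rest marker detection
#'
#' For every cluster, a gene is tested iff it is expressed (count > 0) in at
#' least `min_pct` of the cells of the cluster or of the rest (the
#' either-group rule; set `pct_rule = "both"` to require both), and the
#' absolute log fold change of mean normalized expression is at least
#' `logfc_min`. The fold change is computed on the de-logged scale,
#' `ln(mean(expm1(x_in)) + 1) - ln(mean(expm1(x_out)) + 1)`. Passing genes
#' are tested cluster-versus-rest with a two-sided Wilcoxon rank-sum test
#' (tie-aware exact enumeration when both sides have at most `exact_max_n`
#' cells, tie- and continuity-corrected normal approximation otherwise), and
#' Bonferroni-adjusted over the genes tested within the cluster.
#'
#' @param norm genes x cells normalized matrix from [logNormalize()].
#' @param clusters cluster label per cell (at least 2 clusters, each with at
#'   least 3 cells).
#' @param min_pct expression-fraction gate (default 0.25).
#' @param logfc_min log-fold-change gate (default 0.25, natural log).
#' @param pct_rule `"either"` (default) or `"both"`.
#' @param exact_max_n largest per-side size for the exact enumeration path.
#' @return a [S4Vectors::DataFrame] with columns `gene`, `cluster`,
#'   `p_value`, `p_adj`, `logFC`, `pct_in`, `pct_out`, ordered by cluster
#'   then p-value.
#' @export
findMarkers <- function(norm, clusters, min_pct = 0.25, logfc_min = 0.25,
                        pct_rule = c("either", "both"), exact_max_n = 20) {
  pct_rule <- match.arg(pct_rule)
  m <- .countsOf(norm)
  clusters <- as.character(clusters)
  if (length(clusters) != ncol(m))
    stop("'clusters' must have one label per cell")
  cl <- sort(unique(clusters))
  if (length(cl) < 2L) stop("no contrast: need at least 2 clusters")
  sizes <- table(clusters)
  if (any(sizes < 3L))
    stop("every cluster needs at least 3 cells")
  dense <- as.matrix(m)
  pos <- dense > 0
  res <- vector("list", length(cl))
  for (i in seq_along(cl)) {
    ing <- clusters == cl[i]
    pct_in <- rowMeans(pos[, ing, drop = FALSE])
    pct_out <- rowMeans(pos[, !ing, drop = FALSE])
    mean_in <- rowMeans(expm1(dense[, ing, drop = FALSE]))
    mean_out <- rowMeans(expm1(dense[, !ing, drop = FALSE]))
    lfc <- log(mean_in + 1) - log(mean_out + 1)
    pass_pct <- if (pct_rule == "either")
      pmax(pct_in, pct_out) >= min_pct
    else pmin(pct_in, pct_out) >= min_pct
    keep <- which(pass_pct & abs(lfc) >= logfc_min)
    if (length(keep) == 0L) {
      res[[i]] <- NULL
      next
    }
    p <- .ranksumP(dense[keep, , drop = FALSE], ing, exact_max_n)
    ord <- order(p, rownames(dense)[keep])
    res[[i]] <- DataFrame(
      gene = rownames(dense)[keep][ord],
      cluster = cl[i],
      p_value = unname(p[ord]),
      p_adj = pmin(1, unname(p[ord]) * length(keep)),
      logFC = unname(lfc[keep][ord]),
      pct_in = unname(pct_in[keep][ord]),
      pct_out = unname(pct_out[keep][ord]))
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out))
    out <- DataFrame(gene = character(0), cluster = character(0),
                     p_value = numeric(0), p_adj = numeric(0),
                     logFC = numeric(0), pct_in = numeric(0),
                     pct_out = numeric(0))
  out
}

#' Flag suspected doublet clusters by shared-marker overlap
#'
#' A droplet capturing two cells yields a hybrid profile that forms a small
#' cluster sharing feature genes with its two parent clusters. A cluster is
#' flagged iff it holds at most `max_frac` of all cells (default 5\%, the
#' usual droplet doublet-rate estimate) and its positive-marker set has
#' Jaccard overlap at least `jaccard_min` with the marker sets of at least
#' two distinct larger clusters.
#'
#' The default `jaccard_min` of 0.15 reflects that even an ideal half-half
#' mixture, whose marker set is exactly the union of its two parents' sets,
#' reaches Jaccard at most ~0.5 against each parent; with detection noise at
#' half depth true parent overlaps land around 0.2--0.45, while unrelated
#' clusters overlap near 0.
#'
#' @param markers marker table from [findMarkers()].
#' @param clusters cluster label per cell (defines cluster sizes).
#' @param max_frac size-exemption fraction (default 0.05).
#' @param jaccard_min minimum marker-set Jaccard overlap (default 0.15).
#' @param alpha adjusted-p cutoff defining a cluster's marker set.
#' @return character vector of flagged cluster ids.
#' @export
flagDoubletClusters <- function(markers, clusters, max_frac = 0.05,
                                jaccard_min = 0.15, alpha = 0.05) {
  clusters <- as.character(clusters)
  sizes <- table(clusters)
  sig <- markers[markers$p_adj < alpha & markers$logFC > 0, , drop = FALSE]
  sets <- split(sig$gene, sig$cluster)
  flagged <- character(0)
  for (cc in names(sizes)) {
    if (sizes[[cc]] > max_frac * length(clusters)) next
    mc <- sets[[cc]]
    if (is.null(mc) || length(mc) == 0L) next
    larger <- names(sizes)[sizes > sizes[[cc]]]
    hits <- 0L
    for (d in larger) {
      md <- sets[[d]]
      if (is.null(md) || length(md) == 0L) next
      jac <- length(intersect(mc, md)) / length(union(mc, md))
      if (jac >= jaccard_min) hits <- hits + 1L
    }
    if (hits >= 2L) flagged <- c(flagged, cc)
  }
  flagged
}

#' Annotate clusters by correlation with reference expression profiles
#'
#' Computes the Pearson correlation between each cluster's averaged
#' expression profile and each reference (e.g. bulk RNA-seq of sorted cell
#' populations) over the shared gene universe, and assigns every cluster
#' the best-correlated reference label (ties broken lexicographically).
#'
#' @param cluster_means genes x clusters matrix of averaged expression.
#' @param reference_profiles genes x labels reference matrix.
#' @return a [S4Vectors::DataFrame] with columns `cluster`, `label`,
#'   `r_best`; the full cluster x reference correlation matrix is attached
#'   as `metadata()$cor`.
#' @export
annotateByReference <- function(cluster_means, reference_profiles) {
  shared <- intersect(rownames(cluster_means), rownames(reference_profiles))
  if (length(shared) < 3L)
    stop("fewer than 3 genes shared with the reference profiles")
  r <- suppressWarnings(cor(as.matrix(cluster_means[shared, , drop = FALSE]),
                            as.matrix(reference_profiles[shared, ,
                                                         drop = FALSE])))
  r[is.na(r)] <- 0
  best <- vapply(seq_len(nrow(r)), function(i) {
    mx <- max(r[i, ])
    sort(colnames(r)[r[i, ] == mx])[1L]
  }, character(1))
  out <- DataFrame(cluster = rownames(r), label = best,
                   r_best = r[cbind(seq_len(nrow(r)), match(best, colnames(r)))])
  S4Vectors::metadata(out)$cor <- r
  out
}
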