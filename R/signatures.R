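# Multi-set signature intersection statistics and co-expression modules.

#' Venn decomposition of a gene-set collection
#'
#' Counts every one of the \eqn{2^m - 1} membership regions of m sets
#' (2 <= m <= 6): for each non-empty subset of sets, the number of genes
#' belonging to exactly those sets. Region names join the member set names
#' with `&`; the all-sets region is the full intersection.
#'
#' @param sets a [GeneSetCollection-class].
#' @return named integer vector of region counts (all regions reported,
#'   including empty ones); counts sum to the size of the union.
#' @examples
#' gsc <- geneSetCollection(list(A = c("g1", "g2"), B = c("g2", "g3")),
#'                          universe = paste0("g", 1:5))
#' vennDecompose(gsc)
#' @export
vennDecompose <- function(sets) {
  stopifnot(is(sets, "GeneSetCollection"))
  m <- length(sets@sets)
  if (m < 2L || m > 6L) stop("need between 2 and 6 sets")
  validObject(sets)
  un <- unique(unlist(sets@sets, use.names = FALSE))
  member <- vapply(sets@sets, function(s) un %in% s,
                   logical(length(un)))
  if (length(un) == 1L) member <- matrix(member, 1L)
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), m))[-1L, , drop = FALSE]
  nm <- names(sets@sets)
  counts <- apply(patterns, 1L, function(pt) {
    sum(apply(member, 1L, function(row) all(row == as.logical(pt))))
  })
  names(counts) <- apply(patterns, 1L, function(pt)
    paste(nm[as.logical(pt)], collapse = "&"))
  as.integer(counts) -> out
  names(out) <- names(counts)
  out
}

#' Full-intersection size of a gene-set collection
#'
#' @param sets a [GeneSetCollection-class].
#' @return size of the intersection of all sets.
#' @export
fullIntersectionSize <- function(sets) {
  length(Reduce(intersect, sets@sets))
}

#' Size-matched permutation test for a multi-way intersection
#'
#' Tests whether the sets share more genes than size-matched random pools
#' would. Each of `B` null draws samples, for every set, a random gene pool
#' of the same size — uniformly, without replacement within a set,
#' independently across sets and draws — from the null universe, and
#' records the full-intersection size. Reported are the upper-tail
#' empirical p-value \eqn{(1 + \#\{null \ge obs\})/(1 + B)} and a
#' Student-t p-value for the deviation of the observed size from the
#' permutation distribution (see [permutationConcordanceTest()] for the
#' convention and its caveat). The analytic null mean is
#' \eqn{U \prod_i (s_i/U)} for independent uniform sets.
#'
#' @param sets a [GeneSetCollection-class].
#' @param B number of null draws (default 1000).
#' @param seed integer seed.
#' @param null_universe `"universe"` (default: sample from the collection's
#'   declared universe, typically all detected genes) or `"union"` (sample
#'   from the union of the observed sets).
#' @return an [IntersectionTestResult-class] carrying the Venn region
#'   counts, the observed full-intersection size, the null sample and both
#'   p-values.
#' @export
intersectionPermutationTest <- function(sets, B = 1000, seed = 1,
                                        null_universe = c("universe",
                                                          "union")) {
  stopifnot(is(sets, "GeneSetCollection"))
  null_universe <- match.arg(null_universe)
  if (B < 2L) stop("'B' must be at least 2")
  validObject(sets)
  uni <- if (null_universe == "universe") sets@universe
  else unique(unlist(sets@sets, use.names = FALSE))
  sizes <- lengths(sets@sets)
  if (any(sizes > length(uni)))
    stop("a set is larger than the null universe")
  obs <- fullIntersectionSize(sets)
  regions <- vennDecompose(sets)
  U <- length(uni)
  withSeed(deriveSeed(seed, "intersection"), {
    null <- vapply(seq_len(B), function(i) {
      draw <- lapply(sizes, function(s) sample.int(U, s))
      length(Reduce(intersect, draw))
    }, numeric(1))
    p_emp <- (1 + sum(null >= obs)) / (1 + B)
    new("IntersectionTestResult", statistic = "full_intersection_size",
        observed = as.numeric(obs), null = null, p_empirical = p_emp,
        p_ttest = tTestAgainstNull(null, obs), B = as.integer(B),
        seed = as.integer(seed), regions = regions,
        null_mean = mean(null), null_sd = sd(null))
  })
}

#' Gene-gene co-expression modules
#'
#' Pearson correlation of every gene pair across the selected cells,
#' followed by average-linkage hierarchical clustering on the distance
#' `1 - r`, cut into `n_modules` modules. Genes with zero variance across
#' the selected cells get correlation 0 by convention and are flagged.
#'
#' @param expr genes x cells normalized expression matrix.
#' @param genes gene ids to correlate (>= 2).
#' @param cells optional cell ids or logical/integer index selecting the
#'   cell subset (default: all cells).
#' @param n_modules number of modules to cut the dendrogram into
#'   (default 2).
#' @return a [CorrelationModules-class].
#' @export
coexpressionModules <- function(expr, genes = rownames(expr), cells = NULL,
                                n_modules = 2) {
  m <- .countsOf(expr)
  if (!all(genes %in% rownames(m))) stop("unknown gene ids in 'genes'")
  if (length(genes) < 2L) stop("need at least 2 genes")
  sub <- m[genes, , drop = FALSE]
  if (!is.null(cells)) sub <- sub[, cells, drop = FALSE]
  if (ncol(sub) < 3L) stop("need at least 3 cells")
  x <- t(as.matrix(sub))
  zv <- colnames(x)[apply(x, 2L, sd) == 0]
  r <- suppressWarnings(cor(x))
  r[is.na(r)] <- 0
  diag(r) <- 1
  hc <- hclust(as.dist(1 - r), method = "average")
  mods <- cutree(hc, k = min(n_modules, length(genes)))
  new("CorrelationModules", cor = r, modules = as.integer(mods),
      n_modules = as.integer(n_modules), zero_variance = zv,
      linkage = "average") -> out
  names(out@modules) <- names(mods)
  out
}
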