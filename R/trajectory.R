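# Statistics on pseudotime orderings: concordance of two orderings with a
# permutation null, and monotone trend tests along pseudotime.

.alignOrderings <- function(a, b) {
  av <- if (is.data.frame(a)) setNames(a[[2L]], a[[1L]]) else a
  bv <- if (is.data.frame(b)) setNames(b[[2L]], b[[1L]]) else b
  if (!is.null(names(av)) && !is.null(names(bv))) {
    if (!setequal(names(av), names(bv)))
      stop("the two orderings cover different cell sets")
    bv <- bv[names(av)]
  } else if (length(av) != length(bv)) {
    stop("the two orderings cover different cell sets")
  }
  if (length(av) < 3L) stop("need at least 3 cells")
  list(a = as.numeric(av), b = as.numeric(bv))
}

#' Spearman concordance of two pseudotime orderings
#'
#' Spearman rank correlation (average-rank tie handling) between two
#' orderings of the same cells, e.g. the pseudotimes inferred by two
#' independent trajectory methods.
#'
#' @param a,b orderings: named numeric vectors (names = cell ids) or
#'   two-column data.frames (cell id, value). Unnamed vectors are matched by
#'   position.
#' @return signed Spearman rho.
#' @export
orderingConcordance <- function(a, b) {
  o <- .alignOrderings(a, b)
  cor(rank(o$a), rank(o$b))
}

#' Permutation test for ordering concordance
#'
#' Builds a null distribution of Spearman rho by randomly shuffling the
#' second ordering's values `B` times (default 1000), and reports both the
#' empirical p-value \eqn{(1 + \#\{|null| \ge |obs|\})/(1 + B)} and a
#' Student-t p-value for the deviation of the observed rho from the
#' permutation distribution (\eqn{t = (\rho - \bar{null})/sd(null)},
#' \eqn{B - 1} df). Because the sign of a pseudotime axis is arbitrary
#' between methods, significance is assessed on \eqn{|\rho|}; the signed
#' rho is reported alongside. The t-based p assumes a roughly Gaussian
#' null and is kept for comparability with published practice; the
#' empirical p-value, whose resolution is honestly bounded at
#' \eqn{1/(B+1)}, is the recommended summary.
#'
#' @inheritParams orderingConcordance
#' @param B number of shuffles (default 1000).
#' @param seed integer seed.
#' @return a [ConcordanceResult-class].
#' @export
permutationConcordanceTest <- function(a, b, B = 1000, seed = 1) {
  o <- .alignOrderings(a, b)
  if (B < 2L) stop("'B' must be at least 2")
  ra <- rank(o$a)
  rb <- rank(o$b)
  obs <- cor(ra, rb)
  withSeed(deriveSeed(seed, "concordance"), {
    null <- vapply(seq_len(B), function(i) cor(ra, sample(rb)), numeric(1))
    p_emp <- (1 + sum(abs(null) >= abs(obs))) / (1 + B)
    new("ConcordanceResult", statistic = "spearman_rho",
        observed = obs, null = null, p_empirical = p_emp,
        p_ttest = tTestAgainstNull(null, obs), B = as.integer(B),
        seed = as.integer(seed), rho_signed = obs, rho_abs = abs(obs))
  })
}

#' Trend of a per-cell quantity along pseudotime
#'
#' Spearman correlation of a per-cell quantity (total UMI, detected genes,
#' a gene's expression, ...) against pseudotime, with the asymptotic
#' t-approximation p-value. Constant inputs make rho undefined; by
#' convention rho = 0 with p = 1 is returned with `degenerate = TRUE`.
#'
#' @param values numeric per-cell quantity, named by cell id or aligned
#'   with `order`.
#' @param order pseudotime ordering (named numeric vector or two-column
#'   data.frame).
#' @return list with `rho`, `p`, `n` and `degenerate`.
#' @export
pseudotimeTrend <- function(values, order) {
  o <- .alignOrderings(values, order)
  n <- length(o$a)
  if (sd(o$a) == 0 || sd(o$b) == 0)
    return(list(rho = 0, p = 1, n = n, degenerate = TRUE))
  rho <- cor(rank(o$a), rank(o$b))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n, degenerate = FALSE)
}
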