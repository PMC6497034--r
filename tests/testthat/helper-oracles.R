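# Independent brute-force oracles used to check the package's optimized
# implementations on tiny inputs.

# Two-sided rank-sum p by exhaustive enumeration of all C(n, n1) group
# assignments (tie-aware: ranks are the observed average ranks).
bruteWilcoxP <- function(x, in_group) {
  n <- length(x)
  n1 <- sum(in_group)
  r <- rank(x)
  w_obs <- sum(r[in_group])
  combs <- combn(n, n1)
  ws <- apply(combs, 2L, function(idx) sum(r[idx]))
  mu <- mean(ws)
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# QC survivor set by direct evaluation of the three removal rules.
bruteQCKeep <- function(detected, mito, min_genes, max_genes, max_mito) {
  keep <- logical(length(detected))
  for (i in seq_along(detected)) {
    removed <- detected[i] < min_genes || detected[i] > max_genes ||
      mito[i] > max_mito
    keep[i] <- !removed
  }
  keep
}

# Venn region counts by per-gene membership tally over the union.
bruteVenn <- function(sets) {
  un <- unique(unlist(sets))
  out <- integer(0)
  m <- length(sets)
  for (size in seq_len(m)) {
    cmb <- combn(m, size)
    for (pick in seq_len(ncol(cmb))) {
      members <- cmb[, pick]
      rest <- setdiff(seq_len(m), members)
      cnt <- 0L
      for (g in un) {
        inset <- vapply(sets, function(s) g %in% s, logical(1))
        if (all(inset[members]) && !any(inset[rest])) cnt <- cnt + 1L
      }
      out[paste(names(sets)[members], collapse = "&")] <- cnt
    }
  }
  out
}

# Plain Rand index between two partitions.
randIndex <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, `==`)
  same_b <- outer(b, b, `==`)
  ut <- upper.tri(same_a)
  mean(same_a[ut] == same_b[ut])
}

# Exact distribution of the 4-way intersection size of independent uniform
# random subsets of sizes s from a universe of size U, via the chain
# |S1 n S2| ~ Hyper, |(S1 n S2) n S3| ~ Hyper, ... conditioned sizes.
exactIntersectionPMF <- function(U, sizes) {
  pmf <- setNames(1, as.character(sizes[1L]))
  for (s in sizes[-1L]) {
    nxt <- numeric(0)
    for (a in names(pmf)) {
      av <- as.integer(a)
      ks <- 0:min(av, s)
      pr <- stats::dhyper(ks, av, U - av, s)
      for (j in seq_along(ks)) {
        key <- as.character(ks[j])
        nxt[key] <- (if (key %in% names(nxt)) nxt[key] else 0) +
          pmf[[a]] * pr[j]
      }
    }
    pmf <- nxt
  }
  pmf
}

# Draw from that exact distribution without constructing sets.
sampleIntersectionChain <- function(B, U, sizes) {
  vapply(seq_len(B), function(i) {
    a <- sizes[1L]
    for (s in sizes[-1L]) a <- stats::rhyper(1, a, U - a, s)
    a
  }, numeric(1))
}

# Small cohort configuration used by several tests.
smallConfig <- function(seed, ...) {
  simConfig(cells_per_batch = 150, n_genes = 600, seed = seed, ...)
}
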