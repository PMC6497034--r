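# kNN alignment score: quantitative evaluation of batch mixing in a
# low-dimensional embedding.

#' Alignment score from a mean same-batch neighbour count
#'
#' The normalized batch-mixing score
#' \eqn{1 - (\bar x - k/N)/(k - k/N)}, clamped to [0, 1]. With perfectly
#' segregated batches every neighbour is same-batch (\eqn{\bar x = k}) and
#' the score is 0; with perfectly mixed equal batches
#' \eqn{\bar x = k/N} in expectation and the score is 1.
#'
#' @param x_bar mean same-batch neighbour count, in [0, k].
#' @param k neighbourhood size.
#' @param N number of batches (>= 2).
#' @return the score in [0, 1].
#' @examples
#' alignmentScoreFromXbar(100, k = 100, N = 4)  # segregated -> 0
#' alignmentScoreFromXbar(200, k = 800, N = 4)  # x_bar = k/N -> 1
#' @export
alignmentScoreFromXbar <- function(x_bar, k, N) {
  if (N < 2L) stop("'N' must be at least 2")
  if (k < 1L) stop("'k' must be at least 1")
  if (any(x_bar < 0 | x_bar > k)) stop("'x_bar' must lie in [0, k]")
  pmin(1, pmax(0, 1 - (x_bar - k / N) / (k - k / N)))
}

# Balanced subsample: every batch down to the minimum batch size, without
# replacement.  Returns integer cell indices.
.balancedSample <- function(batch) {
  idx <- split(seq_along(batch), batch)
  m <- min(lengths(idx))
  unlist(lapply(idx, function(i) if (length(i) == m) i else sample(i, m)),
         use.names = FALSE)
}

# For each subsampled cell, the same-batch indicator of its j-th nearest
# neighbour (exact Euclidean kNN, self excluded, ties broken by cell index).
.sameBatchNeighbourMatrix <- function(coords, batch, idx, k) {
  co <- coords[idx, , drop = FALSE]
  bt <- as.integer(factor(batch[idx]))
  n <- nrow(co)
  sq <- rowSums(co^2)
  D2 <- -2 * tcrossprod(co) + sq
  D2 <- t(D2) + sq
  diag(D2) <- Inf
  same <- matrix(FALSE, n, k)
  for (i in seq_len(n)) {
    nb <- order(D2[i, ])[seq_len(k)]
    same[i, ] <- bt[nb] == bt[i]
  }
  same
}

.resolveEmbedding <- function(x, batch) {
  coords <- as.matrix(x)
  if (!all(is.finite(coords))) stop("embedding coordinates must be finite")
  batch <- as.character(batch)
  if (length(batch) != nrow(coords))
    stop("'batch' must have one label per cell")
  list(coords = coords, batch = batch)
}

#' Alignment score of a batch-labelled embedding
#'
#' Subsamples every batch to the smallest batch size (without replacement,
#' seeded), builds the exact Euclidean k-nearest-neighbour graph on the
#' subsample (self excluded, distance ties broken by cell index), computes
#' the mean number of same-batch cells among each sampled cell's k
#' neighbours (\eqn{\bar x}), and returns the normalized score
#' \eqn{1 - (\bar x - k/N)/(k - k/N)} clamped to [0, 1]. Cells of
#' batch-exclusive populations can be masked beforehand via `exclude`.
#'
#' @param x embedding coordinates, cells x d (d >= 1), rownames = cell ids.
#' @param batch batch label per cell (>= 2 batches).
#' @param k neighbourhood size; must be smaller than the subsample total.
#' @param seed integer seed for the subsampling.
#' @param repeats number of independent subsampling repeats to average
#'   (default 1).
#' @param exclude optional cell ids to drop before subsampling.
#' @return an [AlignmentScore-class].
#' @export
alignmentScore <- function(x, batch, k, seed = 1, repeats = 1,
                           exclude = NULL) {
  e <- .resolveEmbedding(x, batch)
  if (!is.null(exclude)) {
    keep <- !(rownames(e$coords) %in% exclude)
    e$coords <- e$coords[keep, , drop = FALSE]
    e$batch <- e$batch[keep]
  }
  N <- length(unique(e$batch))
  if (N < 2L) stop("'batch' must contain at least 2 batches")
  m <- min(table(e$batch))
  if (k >= m * N)
    stop(sprintf("k (%d) must be smaller than the subsample total (%d)",
                 k, m * N))
  if (k < 1L) stop("'k' must be at least 1")
  withSeed(deriveSeed(seed, "alignment"), {
    xb <- sc <- numeric(repeats)
    for (r in seq_len(repeats)) {
      idx <- .balancedSample(e$batch)
      same <- .sameBatchNeighbourMatrix(e$coords, e$batch, idx, k)
      xb[r] <- mean(rowSums(same))
      sc[r] <- alignmentScoreFromXbar(xb[r], k, N)
    }
    new("AlignmentScore", k = as.integer(k), N = as.integer(N),
        x_bar = mean(xb), score = mean(sc), n_sampled_per_batch = as.integer(m),
        repeats = as.integer(repeats), seed = as.integer(seed))
  })
}

#' Alignment-score sweep over neighbourhood sizes
#'
#' Computes the alignment score for each `k` in `k_values` on one shared
#' seeded subsample, so scores are comparable across k. Sweeping k (e.g.
#' 100 to 1000) checks that a method ranking is not an artefact of the
#' arbitrary neighbourhood size.
#'
#' @inheritParams alignmentScore
#' @param k_values neighbourhood sizes, all smaller than the subsample
#'   total.
#' @return a list of [AlignmentScore-class], one per k, named by k.
#' @export
kSweep <- function(x, batch, k_values, seed = 1, exclude = NULL) {
  if (length(k_values) == 0L) stop("'k_values' must not be empty")
  e <- .resolveEmbedding(x, batch)
  if (!is.null(exclude)) {
    keep <- !(rownames(e$coords) %in% exclude)
    e$coords <- e$coords[keep, , drop = FALSE]
    e$batch <- e$batch[keep]
  }
  N <- length(unique(e$batch))
  if (N < 2L) stop("'batch' must contain at least 2 batches")
  m <- min(table(e$batch))
  kmax <- max(k_values)
  if (kmax >= m * N)
    stop(sprintf("max k (%d) must be smaller than the subsample total (%d)",
                 kmax, m * N))
  withSeed(deriveSeed(seed, "alignment"), {
    idx <- .balancedSample(e$batch)
    same <- .sameBatchNeighbourMatrix(e$coords, e$batch, idx, kmax)
    cum <- t(apply(same, 1L, cumsum))
    out <- lapply(k_values, function(k) {
      xb <- mean(cum[, k])
      new("AlignmentScore", k = as.integer(k), N = as.integer(N),
          x_bar = xb, score = alignmentScoreFromXbar(xb, k, N),
          n_sampled_per_batch = as.integer(m), repeats = 1L,
          seed = as.integer(seed))
    })
    names(out) <- as.character(k_values)
    out
  })
}

#' Compare batch-correction methods by alignment score
#'
#' Scores several embeddings of the same cells (e.g. the outputs of
#' different correction algorithms) with a single shared subsample and seed
#' so the comparison is paired, and ranks them by decreasing score.
#'
#' @param embeddings named list of cells x d coordinate matrices with
#'   identical cell-id rownames.
#' @param batch batch label per cell, named by cell id or aligned with the
#'   first embedding's rows.
#' @inheritParams alignmentScore
#' @return a [S4Vectors::DataFrame] with columns `method`, `score`, `x_bar`,
#'   sorted by decreasing score.
#' @export
compareMethods <- function(embeddings, batch, k, seed = 1, exclude = NULL) {
  if (length(embeddings) < 1L || is.null(names(embeddings)))
    stop("'embeddings' must be a non-empty named list")
  ids <- rownames(embeddings[[1L]])
  if (is.null(ids)) stop("embeddings need cell-id rownames")
  for (nm in names(embeddings))
    if (!setequal(rownames(embeddings[[nm]]), ids))
      stop(sprintf("embedding '%s' has a different cell set", nm))
  if (is.null(names(batch))) names(batch) <- ids
  if (!is.null(exclude)) ids <- setdiff(ids, exclude)
  bt <- as.character(batch[ids])
  N <- length(unique(bt))
  if (N < 2L) stop("'batch' must contain at least 2 batches")
  m <- min(table(bt))
  if (k >= m * N)
    stop(sprintf("k (%d) must be smaller than the subsample total (%d)",
                 k, m * N))
  withSeed(deriveSeed(seed, "alignment"), {
    sub_ids <- ids[.balancedSample(bt)]
    res <- lapply(names(embeddings), function(nm) {
      co <- embeddings[[nm]][sub_ids, , drop = FALSE]
      same <- .sameBatchNeighbourMatrix(co, batch[sub_ids],
                                        seq_along(sub_ids), k)
      xb <- mean(rowSums(same))
      c(score = alignmentScoreFromXbar(xb, k, N), x_bar = xb)
    })
    out <- DataFrame(method = names(embeddings),
                     score = vapply(res, `[[`, numeric(1), "score"),
                     x_bar = vapply(res, `[[`, numeric(1), "x_bar"))
    out[order(-out$score), , drop = FALSE]
  })
}
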