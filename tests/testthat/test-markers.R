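library(SummarizedExperiment)

test_that("log-normalization has the stated closed forms", {
  m <- matrix(c(0, 7, 0, 0), 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  norm <- logNormalize(m, scale = 1e4)
  expect_identical(as.numeric(norm["g1", "a"]), 0)
  # single-gene cell: ln(1 + scale)
  expect_equal(as.numeric(norm["g2", "a"]), log(10001))
  # all-zero cell maps to zeros
  expect_identical(as.numeric(norm[, "b"]), c(0, 0))
  # column sums of expm1 equal the scale factor for nonzero cells
  sce <- simulateCohort(smallConfig(seed = 3))
  nm <- logNormalize(sce, scale = 500)
  cs <- Matrix::colSums(expm1(nm))
  nz <- Matrix::colSums(assay(sce)) > 0
  expect_true(all(abs(cs[nz] - 500) < 1e-6))
})

test_that("exact rank-sum p-values equal exhaustive enumeration", {
  set.seed(42)
  for (rep in 1:20) {
    n1 <- sample(3:6, 1)
    n2 <- sample(3:8, 1)
    # heavy ties, like sparse UMI data
    x <- sample(0:3, n1 + n2, replace = TRUE)
    g <- rep(c(TRUE, FALSE), c(n1, n2))
    expect_equal(scMixStats:::.ranksumExactP(x, g), bruteWilcoxP(x, g))
  }
  # 3-vs-3 toy: p over all C(6,3) assignments
  x <- c(5, 6, 7, 1, 2, 3)
  g <- rep(c(TRUE, FALSE), each = 3)
  expect_equal(scMixStats:::.ranksumExactP(x, g), 2 / choose(6, 3))
})

test_that("the normal-approximation path matches wilcox.test on large groups", {
  set.seed(7)
  X <- matrix(rpois(40 * 120, 1.5), 40)
  g <- rep(c(TRUE, FALSE), c(50, 70))
  mine <- scMixStats:::.ranksumApproxP(X, g)
  ref <- apply(X, 1L, function(x)
    suppressWarnings(wilcox.test(x[g], x[!g])$p.value))
  expect_equal(mine, unname(ref), tolerance = 1e-10)
})

test_that("marker detection applies the expression and fold-change gates", {
  set.seed(11)
  n <- 40
  cl <- rep(c("A", "B"), each = n / 2)
  m <- matrix(rpois(6 * n, 2) + 0.0, 6, n,
              dimnames = list(sprintf("g%d", 1:6), sprintf("c%d", 1:n)))
  m["g1", ] <- ifelse(cl == "A", 5, 0)       # clean marker of A
  m["g3", ] <- ifelse(cl == "A", 0, 5)       # balances library sizes
  m["g2", ] <- rep(2, n)                     # identically distributed
  norm <- logNormalize(m, 100)
  mk <- findMarkers(norm, cl, min_pct = 0.25, logfc_min = 0.25)
  g1a <- mk[mk$gene == "g1" & mk$cluster == "A", ]
  expect_identical(nrow(g1a), 1L)
  expect_identical(g1a$pct_in, 1)
  expect_identical(g1a$pct_out, 0)
  expect_lt(g1a$p_adj, 0.001)
  # constant gene: filtered by the fold-change gate
  expect_false("g2" %in% mk$gene)
  expect_true(all(mk$p_adj >= mk$p_value))
  expect_error(findMarkers(norm, rep("A", n)), "no contrast")
  expect_error(findMarkers(norm[, 1:4], cl[c(1, 2, 21, 22)]),
               "at least 3 cells")
})

test_that("marker detection is invariant to cell order and label names", {
  sce <- simulateCohort(smallConfig(seed = 23))
  norm <- as.matrix(logNormalize(sce))
  cl <- colData(sce)$cluster
  mk <- findMarkers(norm, cl)
  perm <- sample(ncol(norm))
  mk_p <- findMarkers(norm[, perm], cl[perm])
  expect_identical(as.data.frame(mk), as.data.frame(mk_p))
  relab <- setNames(sprintf("X%02d", seq_along(unique(cl))), sort(unique(cl)))
  mk_r <- findMarkers(norm, unname(relab[cl]))
  expect_identical(mk$gene, mk_r$gene)
  expect_equal(mk$p_value, mk_r$p_value)
  expect_identical(unname(relab[mk$cluster]), mk_r$cluster)
})

test_that("on a randomly split population the test is calibrated", {
  set.seed(31)
  X <- matrix(rnbinom(400 * 200, size = 2, mu = 1.2), 400,
              dimnames = list(sprintf("g%04d", 1:400), NULL))
  norm <- as.matrix(logNormalize(X, 1000))
  cl <- sample(rep(c("A", "B"), each = 100))
  mk <- findMarkers(norm, cl, min_pct = 0, logfc_min = 0)
  pv <- mk$p_value[mk$cluster == "A"]
  rate <- mean(pv < 0.05)
  se <- sqrt(0.05 * 0.95 / length(pv))
  expect_lte(rate, 0.05 + 3 * se)
})

test_that("doublet flagging needs small size plus two-parent overlap", {
  mkrec <- function(cluster, genes) S4Vectors::DataFrame(
    gene = genes, cluster = cluster, p_value = 1e-8, p_adj = 1e-6,
    logFC = 1, pct_in = 1, pct_out = 0.1)
  markers <- rbind(
    mkrec("big1", sprintf("a%d", 1:40)),
    mkrec("big2", sprintf("b%d", 1:40)),
    mkrec("dbl", c(sprintf("a%d", 1:20), sprintf("b%d", 1:20))),
    mkrec("pure", sprintf("p%d", 1:40)))
  cl <- rep(c("big1", "big2", "dbl", "pure"), c(500, 480, 30, 30))
  flagged <- flagDoubletClusters(markers, cl)
  expect_identical(flagged, "dbl")
  # clusters above the ~5% size exemption are never flagged
  cl_big <- rep(c("big1", "big2", "dbl", "pure"), c(300, 300, 100, 30))
  expect_false("dbl" %in% flagDoubletClusters(markers, cl_big))
})

test_that("reference annotation is exact, affine-invariant and tie-stable", {
  set.seed(5)
  ref <- matrix(rexp(30 * 3), 30, 3,
                dimnames = list(sprintf("g%d", 1:30), c("B", "A", "C")))
  cm <- cbind(cl1 = ref[, "A"], cl2 = 2 * ref[, "C"] + 5)
  ann <- annotateByReference(cm, ref)
  expect_identical(ann$label, c("A", "C"))
  expect_equal(ann$r_best, c(1, 1))
  # ties broken lexicographically
  ref_tie <- cbind(Z = ref[, 1], Y = ref[, 1])
  ann_tie <- annotateByReference(cbind(cl = ref[, 1]), ref_tie)
  expect_identical(ann_tie$label, "Y")
  expect_error(annotateByReference(cm[1:2, ], ref[1:2, ]), "3 genes")
})

test_that("clusters of a noisy cohort are annotated to their true type", {
  sce <- simulateCohort(smallConfig(seed = 37))
  norm <- logNormalize(sce)
  cd <- colData(sce)
  singlet <- !cd$is_doublet
  labs <- sort(unique(cd$cluster[singlet]))
  cm <- vapply(labs, function(l)
    Matrix::rowMeans(norm[, cd$cluster == l, drop = FALSE]),
    numeric(nrow(norm)))
  rownames(cm) <- rownames(norm)
  ref <- log1p(metadata(sce)$ground_truth$type_means)
  ann <- annotateByReference(cm, ref)
  expect_gte(mean(ann$label == ann$cluster), 0.95)
})
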