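library(SummarizedExperiment)

test_that("identical config and seed reproduce bit-identical outputs", {
  cfg <- smallConfig(seed = 11)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(as.matrix(assay(a, "counts")), as.matrix(assay(b, "counts")))
  expect_identical(colData(a), colData(b))
  expect_identical(simulateEmbedding(a, 2, seed = 3),
                   simulateEmbedding(b, 2, seed = 3))
  expect_identical(assay(simulateTrajectory(cfg)),
                   assay(simulateTrajectory(cfg)))
  expect_identical(simulateProgramSets(cfg), simulateProgramSets(cfg))
})

test_that("invalid configuration errors name the offending field", {
  expect_error(simConfig(hb_fraction = 1.5), "hb_fraction")
  expect_error(simConfig(libsize_decay = 1), "libsize_decay")
  expect_error(simConfig(nb_dispersion = -1), "nb_dispersion")
  expect_error(simConfig(core_sizes = c(120, 22)), "core_sizes")
  expect_error(simulateEmbedding(data.frame(cell_type = "a", batch = "b"),
                                 batch_shift = -1), "batch_shift")
  expect_error(simulateTrajectory(smallConfig(seed = 1, traj_n_cells = 9)),
               "traj_n_cells")
})

test_that("hemoglobin-high cells appear at the configured rate", {
  cfg <- simConfig(n_batches = 4, cells_per_batch = 2500, n_genes = 100,
                   hb_fraction = 0.0392, doublet_fraction = 0, seed = 21)
  sce <- simulateCohort(cfg)
  n_hb <- sum(colData(sce)$is_hb_high)
  # 10,000 cells at 3.92%: 392 expected, binomial SD ~19.4
  expect_gt(n_hb, 392 - 4 * 19.4)
  expect_lt(n_hb, 392 + 4 * 19.4)
  expect_identical(colData(sce)$cell_type == "NRBC", colData(sce)$is_hb_high)
})

test_that("without batch effects all batches share one distribution", {
  cfg <- simConfig(n_batches = 2, cells_per_batch = 150, n_genes = 300,
                   n_cell_types = 1, batch_logfc_sd = 0, hb_fraction = 0,
                   doublet_fraction = 0, seed = 31)
  sce <- simulateCohort(cfg)
  m <- as.matrix(assay(sce, "counts"))
  b1 <- colData(sce)$batch == "B1"
  keep <- rowSums(m) > 0
  pv <- apply(m[keep, ], 1L, function(x)
    suppressWarnings(wilcox.test(x[b1], x[!b1])$p.value))
  rate <- mean(pv < 0.05, na.rm = TRUE)
  # nominal 5%; rank tests on discrete counts run slightly conservative
  expect_gt(sum(keep), 200)
  expect_lt(rate, 0.09)
})

test_that("count marginals match the configured NB mean and variance", {
  cfg <- simConfig(n_batches = 1, cells_per_batch = 2000, n_genes = 300,
                   n_cell_types = 1, batch_logfc_sd = 0, hb_fraction = 0,
                   doublet_fraction = 0, nb_dispersion = 2, seed = 41)
  sce <- simulateCohort(cfg)
  m <- as.matrix(assay(sce, "counts"))
  mu <- metadata(sce)$ground_truth$type_means[, "T1"]
  n <- ncol(m)
  v_theory <- mu + mu^2 / 2
  xbar <- rowMeans(m)
  s2 <- apply(m, 1L, var)
  mean_viol <- abs(xbar - mu) > 3 * sqrt(v_theory / n)
  m4 <- rowMeans((m - xbar)^4)
  se_s2 <- sqrt(pmax(m4 - s2^2, 0) / n)
  var_viol <- abs(s2 - v_theory) > 3 * se_s2
  # ~0.3% of genes may exceed 3 SE by chance
  expect_lte(sum(mean_viol), 5)
  expect_lte(sum(var_viol), 5)
})

test_that("embedding batch shift controls separability and mixing", {
  cfg <- smallConfig(seed = 51)
  sce <- simulateCohort(cfg)
  batch <- colData(sce)$batch
  e0 <- simulateEmbedding(sce, 0, seed = 5)
  e_big <- simulateEmbedding(sce, 50, seed = 5)
  expect_gt(alignScore(alignmentScore(e0, batch, k = 50, seed = 1)), 0.9)
  expect_lt(alignScore(alignmentScore(e_big, batch, k = 50, seed = 1)), 0.05)
  # intermediate shifts: mean score decreasing (small Monte Carlo; the
  # full 20-replicate sweep runs in the acceptance suite)
  ms <- vapply(c(0, 2, 4), function(s) {
    mean(vapply(1:5, function(r)
      alignScore(alignmentScore(simulateEmbedding(sce, s, seed = r),
                                batch, k = 50, seed = r)), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(ms) < 0))
})

test_that("trajectory waves and library-size decay have the planted shape", {
  cfg <- simConfig(traj_n_cells = 600, libsize_decay = 0, n_genes = 600,
                   seed = 61)
  flat <- simulateTrajectory(cfg)
  pt <- colData(flat)$pseudotime
  tot <- Matrix::colSums(assay(flat))
  expect_lt(abs(cor(rank(tot), rank(pt))), 0.15)

  cfg6 <- simConfig(traj_n_cells = 600, libsize_decay = 0.6, n_genes = 600,
                    seed = 61)
  dec <- simulateTrajectory(cfg6)
  pt6 <- colData(dec)$pseudotime
  tot6 <- Matrix::colSums(assay(dec))
  tr <- pseudotimeTrend(tot6, setNames(pt6, colnames(dec)))
  expect_lt(tr$rho, -0.5)
  expect_lt(tr$p, 1e-6)

  # early wave decreases along pseudotime, late wave increases (binned means)
  st <- metadata(dec)$ground_truth$stage_genes
  norm <- logNormalize(dec)
  # the waves are localized bumps, so away from the peak the binned means
  # are near-flat; a rank trend over four bins captures the direction
  bins <- cut(pt6, breaks = seq(0, 1, by = 0.25), include.lowest = TRUE)
  early <- tapply(Matrix::colMeans(norm[st$early, ]), bins, mean)
  late <- tapply(Matrix::colMeans(norm[st$late, ]), bins, mean)
  expect_lt(cor(seq_along(early), early, method = "spearman"), -0.6)
  expect_gt(cor(seq_along(late), late, method = "spearman"), 0.6)
  expect_gt(late[[4]], late[[1]])
  expect_lt(early[[4]], early[[1]])
})

test_that("program sets carry their planted cores and configured sizes", {
  cfg <- simConfig(n_genes = 12000, seed = 71)
  pr <- simulateProgramSets(cfg)
  for (fam in c("gzmb", "gzmk")) {
    sizes <- lengths(geneSets(pr[[fam]]))
    expect_identical(unname(sizes), c(116L, 125L, 134L, 144L))
  }
  core_b <- pr$truth$core_gzmb
  expect_length(core_b, 31L)
  expect_length(pr$truth$core_gzmk, 22L)
  inter <- Reduce(intersect, geneSets(pr$gzmb))
  expect_true(all(core_b %in% inter))
})

test_that("coreless program sets intersect at the analytic product rate", {
  # U = 150 with sizes 116..144 gives a large expected 4-way overlap
  cfg <- simConfig(n_genes = 150, core_sizes = c(0, 0), seed = 81)
  U <- 150
  sizes <- c(116, 125, 134, 144)
  expectation <- U * prod(sizes / U)
  obs <- vapply(1:300, function(i) {
    pr <- simulateProgramSets(simConfig(n_genes = 150, core_sizes = c(0, 0),
                                        seed = 81 + i))
    fullIntersectionSize(pr$gzmb)
  }, numeric(1))
  se <- sd(obs) / sqrt(length(obs))
  expect_lt(abs(mean(obs) - expectation), 3 * se)
})

test_that("sets equal to the universe intersect in the whole universe", {
  uni <- sprintf("g%02d", 1:20)
  gsc <- geneSetCollection(setNames(rep(list(uni), 4),
                                    paste0("S", 1:4)), uni)
  expect_identical(fullIntersectionSize(gsc), 20L)
})

test_that("doublets record two distinct parents and mix their profiles", {
  cfg <- smallConfig(seed = 91)
  sce <- simulateCohort(cfg)
  cd <- colData(sce)
  dbl <- cd$is_doublet
  expect_true(all(cd$parent1[dbl] != cd$parent2[dbl]))
  expect_true(all(is.na(cd$parent1[!dbl])))
  # a doublet group's mean profile is closer to the parent average than to
  # either parent alone
  m <- as.matrix(assay(sce))
  lab <- cd$cell_type
  one <- names(sort(table(lab[dbl]), decreasing = TRUE))[1L]
  pr <- strsplit(sub("DBL:", "", one), "+", fixed = TRUE)[[1L]]
  prof <- function(l) rowMeans(m[, lab == l, drop = FALSE])
  d_mix <- sqrt(sum((prof(one) - (prof(pr[1]) + prof(pr[2])) / 2)^2))
  d_p1 <- sqrt(sum((prof(one) - prof(pr[1]))^2))
  d_p2 <- sqrt(sum((prof(one) - prof(pr[2]))^2))
  expect_lt(d_mix, min(d_p1, d_p2))
})
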