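library(SummarizedExperiment)

test_that("detected-gene mask applies the >= 30-cell rule at the boundary", {
  m <- matrix(0, 3, 31,
              dimnames = list(c("g30", "g29", "g0"), sprintf("c%02d", 1:31)))
  m["g30", 1:30] <- 1
  m["g29", 1:29] <- 5
  mask <- detectedGeneMask(m, min_cells_per_gene = 30)
  expect_true(mask[["g30"]])
  expect_false(mask[["g29"]])
  expect_false(mask[["g0"]])
  # threshold 1 keeps every gene with any count
  expect_identical(unname(detectedGeneMask(m, 1)), c(TRUE, TRUE, FALSE))
  # empty matrix: empty mask, no error
  expect_length(detectedGeneMask(matrix(0, 0, 0)), 0)
  expect_error(detectedGeneMask(m, 0), "min_cells_per_gene")
})

test_that("per-cell QC statistics match a direct tally", {
  m <- matrix(c(5, 5, 0, 0,
                1, 2, 1, 0,
                0, 0, 0, 0), nrow = 4,
              dimnames = list(c("MT-CO1", "GAPDH", "ACTB", "CD3E"),
                              c("cellA", "cellB", "cellZ")))
  qc <- computeCellQC(m)
  expect_identical(qc["cellA", "detected_genes"], 2L)
  expect_identical(qc["cellA", "total_umi"], 10)
  expect_identical(qc["cellA", "mito_fraction"], 0.5)
  # all-zero cell: degenerate convention (0, 0, 0)
  expect_identical(qc["cellZ", "detected_genes"], 0L)
  expect_identical(qc["cellZ", "total_umi"], 0)
  expect_identical(qc["cellZ", "mito_fraction"], 0)
  # 4-gene x 3-cell toy: brute-force recount of every statistic
  for (j in seq_len(ncol(m))) {
    expect_identical(qc$detected_genes[j], sum(m[, j] >= 1))
    expect_identical(qc$total_umi[j], sum(m[, j]))
    expected_mito <- if (sum(m[, j]) > 0) m["MT-CO1", j] / sum(m[, j]) else 0
    expect_identical(qc$mito_fraction[j], expected_mito)
  }
  # detected-gene-share convention
  qc_g <- computeCellQC(m, mito_mode = "genes")
  expect_identical(qc_g["cellB", "mito_fraction"], 1 / 3)
})

test_that("cell filtration applies the three removal rules at boundaries", {
  qc <- S4Vectors::DataFrame(
    detected_genes = c(399L, 400L, 3500L, 3501L, 1000L, 1000L),
    total_umi = rep(5000, 6),
    mito_fraction = c(0.01, 0.05, 0.06, 0.01, 0.061, 0.06),
    row.names = sprintf("c%d", 1:6))
  thr <- qcThresholds(min_genes = 400, max_genes = 3500, max_mito = 0.06)
  kept <- filterCells(qc, thr)
  expect_false("c1" %in% kept)  # 399 detected genes: below 400
  expect_true("c2" %in% kept)   # 400 detected, mito 5% under the 6% cap
  expect_true("c3" %in% kept)   # at both upper boundaries: kept
  expect_false("c4" %in% kept)  # above the gene cap
  expect_false("c5" %in% kept)  # above the mito cap
  expect_true("c6" %in% kept)
  # brute-force rule evaluation over the six-cell fixture
  expect_identical(kept, rownames(qc)[bruteQCKeep(
    qc$detected_genes, qc$mito_fraction, 400, 3500, 0.06)])
  expect_error(qcThresholds(min_genes = 500, max_genes = 400), "min_genes")
})

test_that("filtration is idempotent and invariant to cell order", {
  sce <- simulateCohort(smallConfig(seed = 13))
  counts <- assay(sce, "counts")
  mask <- detectedGeneMask(counts, 10)
  thr <- qcThresholds(min_genes = 50, max_genes = 500, max_mito = 0.06,
                      min_cells_per_gene = 10)
  qc <- computeCellQC(counts[mask, ])
  kept <- filterCells(qc, thr)
  # idempotent: re-running on the survivors changes nothing
  qc2 <- computeCellQC(counts[mask, kept])
  expect_identical(filterCells(qc2, thr), kept)
  # permutation invariant
  perm <- sample(ncol(counts))
  qc_p <- computeCellQC(counts[mask, perm])
  expect_setequal(filterCells(qc_p, thr), kept)
})

test_that("tightening any threshold only shrinks the survivor set", {
  sce <- simulateCohort(smallConfig(seed = 14))
  mask <- detectedGeneMask(sce, 10)
  qc <- computeCellQC(assay(sce, "counts")[mask, ])
  keep_at <- function(max_genes, max_mito)
    filterCells(qc, qcThresholds(50, max_genes, max_mito))
  expect_true(all(keep_at(400, 0.02) %in% keep_at(400, 0.08)))
  expect_true(all(keep_at(300, 0.08) %in% keep_at(500, 0.08)))
  expect_lte(length(keep_at(300, 0.02)), length(keep_at(500, 0.08)))
})

test_that("hemoglobin-high clusters are flagged against the cluster field", {
  # one cluster with 10x hemoglobin signal among 8 clusters
  genes <- c("HBB", "HBG1", "OTHER1", "OTHER2")
  n_per <- 20
  cl <- rep(sprintf("cl%d", 1:8), each = n_per)
  m <- matrix(1, length(genes), length(cl), dimnames = list(genes, NULL))
  m[c("HBB", "HBG1"), cl == "cl3"] <- 10
  expect_identical(flagHemoglobinClusters(m, cl, c("HBB", "HBG1"), 2), "cl3")
  # homogeneous expression: nothing flagged
  m2 <- matrix(1, length(genes), length(cl), dimnames = list(genes, NULL))
  expect_length(flagHemoglobinClusters(m2, cl, c("HBB", "HBG1"), 2), 0)
  expect_error(flagHemoglobinClusters(m, cl, character(0), 2), "hb_genes")
  expect_error(flagHemoglobinClusters(m, rep("one", length(cl)),
                                      c("HBB"), 2), "clusters")
})

test_that("trajectory mito exclusion removes only cells above 2.5%", {
  qc <- S4Vectors::DataFrame(
    detected_genes = rep(500L, 4), total_umi = rep(1000, 4),
    mito_fraction = c(0.026, 0.025, 0.024, 0),
    row.names = c("hi", "edge", "lo", "zero"))
  kept <- trajectoryMitoExclusion(qc)
  expect_identical(kept, c("edge", "lo", "zero"))
  # all below threshold: identity
  expect_identical(trajectoryMitoExclusion(qc[2:4, ]), c("edge", "lo", "zero"))
})

test_that("a 672-cell trajectory with 5 high-mito cells keeps exactly 667", {
  cfg <- simConfig(traj_n_cells = 672, n_genes = 600, seed = 15)
  traj <- simulateTrajectory(cfg, high_mito_cells = 5)
  qc <- computeCellQC(traj)
  kept <- trajectoryMitoExclusion(qc, max_mito = 0.025)
  expect_length(kept, 667)
  expect_setequal(kept, colnames(traj)[!colData(traj)$is_high_mito])
})
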