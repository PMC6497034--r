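#' @importFrom SummarizedExperiment colData rowData assay assays
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SingleCellExperiment SingleCellExperiment
NULL

.MITO_GENES <- c("MT-ND1", "MT-ND2", "MT-CO1", "MT-CO2", "MT-ATP8",
                 "MT-ATP6", "MT-CO3", "MT-ND3", "MT-ND4L", "MT-ND4",
                 "MT-ND5", "MT-ND6", "MT-CYB")
.HB_GENES <- c("HBB", "HBD", "HBG1", "HBG2", "HBA1", "HBA2", "HBM", "HBQ1")

# Gene universe with recognisable mitochondrial and hemoglobin blocks.
.geneUniverse <- function(n_genes) {
  if (n_genes < 100L)
    stop("configuration error: 'n_genes' must be at least 100")
  c(.MITO_GENES, .HB_GENES,
    sprintf("GENE%05d", seq_len(n_genes - length(.MITO_GENES) -
                                  length(.HB_GENES))))
}

# Baseline NB means, log-uniform in the configured range; the mitochondrial
# and hemoglobin blocks are pinned to a modest constant so that healthy
# cells sit well below every mito-fraction threshold.
.baselineMeans <- function(genes, nb_mean_range, mito_mean = 0.5) {
  mu <- exp(runif(length(genes), log(nb_mean_range[1]),
                  log(nb_mean_range[2])))
  names(mu) <- genes
  mu[.MITO_GENES] <- mito_mean
  mu[.HB_GENES] <- 0.5
  mu
}

#' Simulate a multi-batch UMI-count cohort with planted ground truth
#'
#' Draws negative-binomial UMI counts (variance \eqn{\mu + \mu^2/\theta})
#' for discrete cell types across batches. Each cell type up-regulates its
#' own marker-gene block; per-gene multiplicative batch effects are
#' log-normal with SD `batch_logfc_sd`. A hemoglobin-high (NRBC-like)
#' subpopulation is planted at rate `hb_fraction`, and doublet cells are the
#' sum of two distinct parent-type draws at half depth, concentrated in
#' `n_doublet_pairs` parent pairs so that each doublet group forms a small
#' cluster.
#'
#' @param config a [SimConfig-class].
#' @param marker_frac fraction of genes up-regulated per cell type.
#' @param marker_fold multiplicative fold change of a type's marker genes.
#' @param hb_fold fold change of hemoglobin genes in hemoglobin-high cells.
#' @return a [SingleCellExperiment::SingleCellExperiment] with a sparse
#'   `counts` assay (genes x cells), per-cell truth in `colData`
#'   (`batch`, `cell_type`, `cluster`, `is_hb_high`, `is_doublet`,
#'   `parent1`, `parent2`) and global truth in `metadata()$ground_truth`
#'   (type marker lists, expected type mean profiles, hemoglobin and
#'   mitochondrial gene ids).
#' @examples
#' sce <- simulateCohort(simConfig(cells_per_batch = 100, seed = 7))
#' table(SummarizedExperiment::colData(sce)$batch)
#' @export
simulateCohort <- function(config, marker_frac = 0.04, marker_fold = 8,
                           hb_fold = 50) {
  validObject(config)
  withSeed(deriveSeed(config@seed, "cohort"), {
    G <- config@n_genes
    Tn <- config@n_cell_types
    genes <- .geneUniverse(G)
    base <- .baselineMeans(genes, config@nb_mean_range)
    special <- c(.MITO_GENES, .HB_GENES)
    pool <- setdiff(genes, special)

    # type-specific fold matrix; type Tn+1 is the hemoglobin-high population
    fold <- matrix(1, G, Tn + 1L, dimnames = list(genes, NULL))
    n_marker <- max(5L, round(marker_frac * G))
    type_markers <- vector("list", Tn)
    for (t in seq_len(Tn)) {
      mk <- sample(pool, n_marker)
      fold[mk, t] <- marker_fold
      type_markers[[t]] <- mk
    }
    type_labels <- c(sprintf("T%d", seq_len(Tn)), "NRBC")
    names(type_markers) <- type_labels[seq_len(Tn)]
    fold[.HB_GENES, Tn + 1L] <- hb_fold

    if (config@doublet_fraction > 0 && Tn < 2L)
      stop("configuration error: 'doublet_fraction' > 0 needs >= 2 cell types")
    all_pairs <- if (Tn >= 2L) combn(Tn, 2L) else matrix(integer(0), 2, 0)
    n_pairs <- min(config@n_doublet_pairs, ncol(all_pairs))
    pairs <- if (n_pairs > 0L)
      all_pairs[, sample(ncol(all_pairs), n_pairs), drop = FALSE]
    else all_pairs

    batchfac <- matrix(exp(rnorm(G * config@n_batches, 0,
                                 config@batch_logfc_sd)),
                       G, config@n_batches, dimnames = list(genes, NULL))

    n_cells <- config@n_batches * config@cells_per_batch
    batch <- rep(sprintf("B%d", seq_len(config@n_batches)),
                 each = config@cells_per_batch)
    is_hb <- runif(n_cells) < config@hb_fraction
    is_dbl <- !is_hb & runif(n_cells) < config@doublet_fraction &
      n_pairs > 0L
    singlet_type <- sample.int(Tn, n_cells, replace = TRUE)

    parent1 <- parent2 <- rep(NA_character_, n_cells)
    cell_type <- type_labels[singlet_type]
    cell_type[is_hb] <- "NRBC"
    if (any(is_dbl)) {
      # doublets are spread evenly over the parent pairs so that every
      # doublet group forms a detectable small cluster
      pair_id <- sample(rep_len(seq_len(n_pairs), sum(is_dbl)))
      p1 <- pairs[1L, pair_id]
      p2 <- pairs[2L, pair_id]
      parent1[is_dbl] <- type_labels[p1]
      parent2[is_dbl] <- type_labels[p2]
      cell_type[is_dbl] <- sprintf("DBL:%s+%s", type_labels[p1],
                                   type_labels[p2])
    }

    counts <- matrix(0, G, n_cells, dimnames = list(genes, NULL))
    theta <- config@nb_dispersion
    for (b in seq_len(config@n_batches)) {
      bmask <- batch == sprintf("B%d", b)
      for (lab in unique(cell_type[bmask])) {
        idx <- which(bmask & cell_type == lab)
        nc <- length(idx)
        if (startsWith(lab, "DBL:")) {
          pr <- strsplit(sub("^DBL:", "", lab), "+", fixed = TRUE)[[1L]]
          mu1 <- base * fold[, match(pr[1L], type_labels)] * batchfac[, b] / 2
          mu2 <- base * fold[, match(pr[2L], type_labels)] * batchfac[, b] / 2
          counts[, idx] <- matrix(rnbinom(G * nc, size = theta, mu = mu1), G) +
            matrix(rnbinom(G * nc, size = theta, mu = mu2), G)
        } else {
          mu <- base * fold[, match(lab, type_labels)] * batchfac[, b]
          counts[, idx] <- matrix(rnbinom(G * nc, size = theta, mu = mu), G)
        }
      }
    }
    cells <- sprintf("%s_C%05d", batch, seq_len(n_cells))
    colnames(counts) <- cells

    type_means <- base * fold
    colnames(type_means) <- type_labels
    sce <- SingleCellExperiment(
      assays = list(counts = Matrix::Matrix(counts, sparse = TRUE)),
      colData = DataFrame(
        batch = batch, cell_type = cell_type, cluster = cell_type,
        is_hb_high = is_hb, is_doublet = is_dbl,
        parent1 = parent1, parent2 = parent2, row.names = cells))
    metadata(sce)$ground_truth <- list(
      type_markers = type_markers, hb_genes = .HB_GENES,
      mito_genes = .MITO_GENES, type_means = type_means,
      doublet_pairs = pairs, config = config)
    sce
  })
}

#' Simulate a low-dimensional embedding with a controllable batch offset
#'
#' Places every cell type at a 2-D Gaussian centre and shifts each batch by
#' an offset of magnitude `batch_shift` in a random direction;
#' `batch_shift = 0` models a perfectly corrected embedding and large values
#' model uncorrected, batch-segregated data.
#'
#' @param truth a `SingleCellExperiment` from [simulateCohort()] or a
#'   data.frame with columns `cell_type` and `batch`.
#' @param batch_shift non-negative magnitude of the per-batch offset, in
#'   units of the within-type SD (1).
#' @param seed integer seed.
#' @param within_sd within-type SD of the Gaussian cloud.
#' @param center_sd SD of the cell-type centre positions.
#' @return numeric matrix (cells x 2) of coordinates, rownames = cell ids.
#' @export
simulateEmbedding <- function(truth, batch_shift = 0, seed = 1,
                              within_sd = 1, center_sd = 8) {
  if (length(batch_shift) != 1L || is.na(batch_shift) || batch_shift < 0)
    stop("'batch_shift' must be a single non-negative real")
  cd <- if (is(truth, "SummarizedExperiment"))
    as.data.frame(colData(truth)) else as.data.frame(truth)
  if (nrow(cd) == 0L) stop("'truth' is empty")
  stopifnot(all(c("cell_type", "batch") %in% colnames(cd)))
  withSeed(deriveSeed(seed, "embedding"), {
    types <- sort(unique(cd$cell_type))
    batches <- sort(unique(cd$batch))
    centers <- matrix(rnorm(2L * length(types), 0, center_sd),
                      ncol = 2L, dimnames = list(types, NULL))
    # offsets point in evenly spaced directions (random global rotation) so
    # any two batches separate once batch_shift dominates the within spread
    ang <- runif(1, 0, 2 * pi) +
      2 * pi * (seq_along(batches) - 1) / length(batches)
    offs <- batch_shift * cbind(cos(ang), sin(ang))
    rownames(offs) <- batches
    xy <- centers[cd$cell_type, , drop = FALSE] +
      offs[as.character(cd$batch), , drop = FALSE] +
      matrix(rnorm(2L * nrow(cd), 0, within_sd), ncol = 2L)
    rownames(xy) <- rownames(cd)
    colnames(xy) <- c("dim1", "dim2")
    xy
  })
}

#' Simulate a maturation trajectory with staged gene waves
#'
#' Cells carry a true pseudotime in [0, 1]. Three gene waves (early,
#' intermediate, late) have unimodal mean curves peaking at pseudotime 0,
#' 0.5 and 1, and the expected library size declines linearly by the factor
#' `1 - libsize_decay` across pseudotime, emulating the loss of
#' transcriptional content during erythroid maturation. Optionally a few
#' cells are planted with strongly elevated mitochondrial expression for
#' exercising the trajectory mito-fraction exclusion rule.
#'
#' @param config a [SimConfig-class] (uses `traj_n_cells`,
#'   `traj_stage_genes`, `libsize_decay`, the NB parameters and `n_genes`).
#' @param high_mito_cells number of cells with planted high mitochondrial
#'   load.
#' @param wave_amp,wave_width amplitude (log scale) and pseudotime width of
#'   the Gaussian wave bumps.
#' @return a `SingleCellExperiment` with `counts`, colData `pseudotime` and
#'   `is_high_mito`, and `metadata()$ground_truth` holding the stage gene
#'   lists.
#' @export
simulateTrajectory <- function(config, high_mito_cells = 0,
                               wave_amp = 1.5, wave_width = 0.18) {
  validObject(config)
  if (config@traj_n_cells < 10L)
    stop("configuration error: 'traj_n_cells' must be >= 10")
  withSeed(deriveSeed(config@seed, "trajectory"), {
    n <- config@traj_n_cells
    G <- config@n_genes
    genes <- .geneUniverse(G)
    # erythroid cells run a low mitochondrial load; keep healthy cells well
    # under the 2.5% exclusion threshold so only planted cells exceed it
    base <- .baselineMeans(genes, config@nb_mean_range, mito_mean = 0.1)
    pool <- setdiff(genes, c(.MITO_GENES, .HB_GENES))
    sizes <- config@traj_stage_genes
    if (sum(sizes) > length(pool))
      stop("configuration error: 'traj_stage_genes' exceed the gene pool")
    picked <- sample(pool, sum(sizes))
    stages <- split(picked, rep(c("early", "intermediate", "late"), sizes))

    pt <- runif(n)
    centers <- c(early = 0, intermediate = 0.5, late = 1)
    logmu <- matrix(log(base), G, n, dimnames = list(genes, NULL))
    for (st in names(stages)) {
      bump <- wave_amp * exp(-((pt - centers[[st]])^2) / (2 * wave_width^2))
      logmu[stages[[st]], ] <- logmu[stages[[st]], ] +
        matrix(bump, length(stages[[st]]), n, byrow = TRUE)
    }
    libfac <- 1 - config@libsize_decay * pt
    mu <- exp(logmu) * matrix(libfac, G, n, byrow = TRUE)

    is_high_mito <- rep(FALSE, n)
    if (high_mito_cells > 0) {
      hm <- sample.int(n, high_mito_cells)
      is_high_mito[hm] <- TRUE
      mu[.MITO_GENES, hm] <- mu[.MITO_GENES, hm] * 25
    }
    counts <- matrix(rnbinom(G * n, size = config@nb_dispersion, mu = mu), G)
    dimnames(counts) <- list(genes, sprintf("TRAJ_C%05d", seq_len(n)))
    sce <- SingleCellExperiment(
      assays = list(counts = Matrix::Matrix(counts, sparse = TRUE)),
      colData = DataFrame(pseudotime = pt, is_high_mito = is_high_mito,
                          row.names = colnames(counts)))
    metadata(sce)$ground_truth <- list(stage_genes = stages, config = config)
    sce
  })
}

#' Simulate two four-set signature-gene program families with planted cores
#'
#' Builds a gene universe of `n_genes` ids and, for each program family
#' (GZMB-like and GZMK-like), four signature sets of the configured sizes.
#' Each set contains the family's planted shared core plus independently
#' sampled private genes, so the observed four-way intersection always
#' contains the core while the size-matched random-pool null does not.
#'
#' @param config a [SimConfig-class] (uses `n_genes`, `program_set_sizes`,
#'   `core_sizes`).
#' @param subtype_names names for the four cytotoxic subtypes.
#' @return list with `gzmb` and `gzmk` [GeneSetCollection-class] objects and
#'   `truth` (the planted core gene vectors).
#' @export
simulateProgramSets <- function(config,
                                subtype_names = c("NK_UCB", "NKT_UCB",
                                                  "NK_PB", "CTL_PB")) {
  validObject(config)
  withSeed(deriveSeed(config@seed, "programs"), {
    universe <- sprintf("G%05d", seq_len(config@n_genes))
    sizes <- config@program_set_sizes
    core_b <- sample(universe, config@core_sizes[1L])
    core_k <- sample(setdiff(universe, core_b), config@core_sizes[2L])
    mkFamily <- function(core, prefix) {
      sets <- lapply(seq_len(4L), function(i) {
        priv <- sample(setdiff(universe, core), sizes[i] - length(core))
        sort(c(core, priv))
      })
      names(sets) <- paste(prefix, subtype_names, sep = "_")
      geneSetCollection(sets, universe)
    }
    list(gzmb = mkFamily(core_b, "GZMB"),
         gzmk = mkFamily(core_k, "GZMK"),
         truth = list(core_gzmb = sort(core_b), core_gzmk = sort(core_k)))
  })
}

#' Simulate normalized expression for two anti-correlated gene programs
#'
#' Produces a continuous (log-normal-scale) expression matrix over the two
#' planted program cores: half the cells express the first program and half
#' the second, yielding positively correlated blocks within a program and
#' anti-correlation between programs — the structure that gene-gene
#' correlation module discovery should recover.
#'
#' @param programs output of [simulateProgramSets()] (the `truth` cores are
#'   used) or a list of two character gene vectors.
#' @param cells_per_program cells expressing each program.
#' @param base,amp,noise_sd baseline level, program elevation and Gaussian
#'   noise SD.
#' @param seed integer seed.
#' @return list with `expr` (genes x cells matrix), `gene_program` (named
#'   factor) and `cell_program`.
#' @export
simulateProgramExpression <- function(programs, cells_per_program = 150,
                                      base = 0.5, amp = 2, noise_sd = 0.3,
                                      seed = 1) {
  cores <- if (!is.null(programs$truth))
    list(A = programs$truth$core_gzmb, B = programs$truth$core_gzmk)
  else list(A = programs[[1L]], B = programs[[2L]])
  withSeed(deriveSeed(seed, "program-expression"), {
    genes <- c(cores$A, cores$B)
    gene_program <- factor(rep(c("A", "B"), c(length(cores$A),
                                              length(cores$B))))
    names(gene_program) <- genes
    n <- 2L * cells_per_program
    cell_program <- factor(rep(c("A", "B"), each = cells_per_program))
    expr <- matrix(base, length(genes), n,
                   dimnames = list(genes, sprintf("PC%04d", seq_len(n))))
    expr[gene_program == "A", cell_program == "A"] <- base + amp
    expr[gene_program == "B", cell_program == "B"] <- base + amp
    expr <- expr + matrix(rnorm(length(expr), 0, noise_sd), nrow(expr))
    expr <- pmax(expr, 0)
    list(expr = expr, gene_program = gene_program,
         cell_program = cell_program)
  })
}
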