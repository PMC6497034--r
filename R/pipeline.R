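# Orchestration: the end-to-end synthetic pipeline with a run manifest.

.stageMsg <- function(stage, ...) message(sprintf("[%s] ", stage), ...)

#' Run the synthetic end-to-end pipeline
#'
#' Executes the enabled stages in dependency order on generator data:
#' `simulate` (cohort counts + ground truth), `qc` (detected-gene mask,
#' per-cell stats, threshold filtering), `integration` (alignment-score
#' comparison of embeddings simulated at several batch-shift levels),
#' `markers` (log-normalization, marker detection on the truth clusters,
#' doublet-cluster flagging, reference-correlation annotation against the
#' generator's expected type profiles), `trajectory` (mito exclusion,
#' pseudotime trend and ordering-concordance permutation test) and
#' `signatures` (program-set Venn decomposition, intersection permutation
#' tests, co-expression modules). All artifacts are written under
#' `out_dir` as Matrix Market / TSV / JSON, plus a `manifest.json` echoing
#' versions, seeds, parameters and per-stage record counts. Rerunning with
#' the same config and seed reproduces identical outputs (the manifest's
#' `timestamp` field aside).
#'
#' @param config a named list (or path to a YAML file with the same
#'   structure): `out_dir`, `seed`, `stages` (subset of the six names
#'   above), and optional per-stage parameter lists `sim`, `qc`
#'   (`min_genes`, `max_genes`, `max_mito`, `min_cells_per_gene`),
#'   `integration` (`batch_shifts` named vector, `k`, `k_sweep`),
#'   `trajectory` (`B`, `high_mito_cells`, `noise_sd`), `signatures` (`B`).
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% stop("config needs 'out_dir'")
  seed <- as.integer(config$seed %||% 1L)
  stages <- config$stages %||% c("simulate", "qc", "integration", "markers",
                                 "trajectory", "signatures")
  known <- c("simulate", "qc", "integration", "markers", "trajectory",
             "signatures")
  if (!all(stages %in% known))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "scMixStats",
                   version = as.character(packageVersion("scMixStats")),
                   seed = seed, stages = as.list(stages),
                   parameters = config[setdiff(names(config),
                                               c("out_dir"))],
                   records = list())
  sim_cfg <- do.call(simConfig, c(config$sim %||% list(), list(seed = seed)))
  sce <- NULL
  kept <- NULL

  if ("simulate" %in% stages) {
    .stageMsg("simulate", "generating cohort")
    sce <- simulateCohort(sim_cfg)
    writeCounts10x(sce, file.path(out_dir, "counts"))
    manifest$records$simulate <- list(genes = nrow(sce), cells = ncol(sce))
  }

  if ("qc" %in% stages) {
    if (is.null(sce)) {
      if (!is.null(config$input_counts)) sce <- readCounts10x(config$input_counts)
      else stop("qc stage is missing its input artifact 'counts' ",
                "(enable the simulate stage or set 'input_counts')")
    }
    .stageMsg("qc", "filtering cells")
    qp <- config$qc %||% list()
    mask <- detectedGeneMask(sce, qp$min_cells_per_gene %||% 30)
    qc <- computeCellQC(assay(sce, "counts")[mask, , drop = FALSE])
    thr <- qcThresholds(min_genes = qp$min_genes %||% 400,
                        max_genes = qp$max_genes %||% 3500,
                        max_mito = qp$max_mito %||% 0.06,
                        min_cells_per_gene = qp$min_cells_per_gene %||% 30)
    kept <- filterCells(qc, thr)
    utils::write.table(cbind(barcode = rownames(qc), as.data.frame(qc)),
                       file.path(out_dir, "qc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines(kept, file.path(out_dir, "kept_barcodes.txt"))
    manifest$records$qc <- list(detected_genes = sum(mask),
                                cells_in = ncol(sce),
                                cells_kept = length(kept))
  }

  if ("integration" %in% stages) {
    if (is.null(sce))
      stop("integration stage is missing its input artifact 'counts' ",
           "(enable the simulate stage)")
    .stageMsg("integration", "scoring embeddings")
    ip <- config$integration %||% list()
    shifts <- ip$batch_shifts %||% c(corrected = 0, partial = 2,
                                     uncorrected = 6)
    k <- ip$k %||% 100
    emb <- lapply(shifts, function(s)
      simulateEmbedding(sce, batch_shift = s,
                        seed = deriveSeed(seed, "emb")))
    cmp <- compareMethods(emb, colData(sce)$batch, k = k,
                          seed = deriveSeed(seed, "score"))
    for (nm in names(emb))
      writeEmbeddingTSV(emb[[nm]],
                        file.path(out_dir, sprintf("embedding_%s.tsv", nm)))
    report <- list(k = k, scores = as.list(setNames(cmp$score, cmp$method)),
                   x_bar = as.list(setNames(cmp$x_bar, cmp$method)))
    if (!is.null(ip$k_sweep)) {
      sw <- kSweep(emb[[1L]], colData(sce)$batch, ip$k_sweep,
                   seed = deriveSeed(seed, "score"))
      report$k_sweep <- lapply(sw, function(a)
        list(k = a@k, score = a@score, x_bar = a@x_bar))
    }
    jsonlite::write_json(report, file.path(out_dir, "integration.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$records$integration <- list(embeddings = length(emb),
                                         best = cmp$method[1L])
  }

  if ("markers" %in% stages) {
    if (is.null(sce) || is.null(kept))
      stop("markers stage is missing its input artifact 'kept_barcodes' ",
           "(enable the qc stage)")
    .stageMsg("markers", "detecting cluster markers")
    sub <- sce[, kept]
    norm <- logNormalize(sub)
    labels <- colData(sub)$cluster
    mk <- findMarkers(norm, labels)
    dbl <- flagDoubletClusters(mk, labels)
    cm <- vapply(sort(unique(labels)), function(l)
      Matrix::rowMeans(norm[, labels == l, drop = FALSE]),
      numeric(nrow(norm)))
    rownames(cm) <- rownames(norm)
    ref <- log1p(metadata(sce)$ground_truth$type_means)
    ann <- annotateByReference(cm, ref)
    utils::write.table(as.data.frame(mk), file.path(out_dir, "markers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(ann),
                       file.path(out_dir, "annotation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines(dbl, file.path(out_dir, "doublet_clusters.txt"))
    manifest$records$markers <- list(markers = nrow(mk),
                                     doublet_clusters = length(dbl))
  }

  if ("trajectory" %in% stages) {
    .stageMsg("trajectory", "pseudotime statistics")
    tp <- config$trajectory %||% list()
    traj <- simulateTrajectory(sim_cfg,
                               high_mito_cells = tp$high_mito_cells %||% 5)
    qc_t <- computeCellQC(traj)
    kept_t <- trajectoryMitoExclusion(qc_t)
    pt <- setNames(colData(traj)$pseudotime, colnames(traj))[kept_t]
    umi <- setNames(qc_t$total_umi, rownames(qc_t))[kept_t]
    genes_per_cell <- setNames(qc_t$detected_genes, rownames(qc_t))[kept_t]
    tr_umi <- pseudotimeTrend(umi, pt)
    tr_genes <- pseudotimeTrend(genes_per_cell, pt)
    alt <- withSeed(deriveSeed(seed, "alt-ordering"),
                    pt + rnorm(length(pt), 0, tp$noise_sd %||% 0.1))
    conc <- permutationConcordanceTest(pt, alt, B = tp$B %||% 1000,
                                       seed = deriveSeed(seed, "conc"))
    jsonlite::write_json(list(
      cells_in = ncol(traj), cells_kept = length(kept_t),
      umi_trend = tr_umi, detected_genes_trend = tr_genes,
      concordance = list(rho = conc@rho_signed,
                         p_empirical = conc@p_empirical,
                         p_ttest = conc@p_ttest, B = conc@B)),
      file.path(out_dir, "trajectory.json"), auto_unbox = TRUE, digits = NA)
    manifest$records$trajectory <- list(cells_kept = length(kept_t))
  }

  if ("signatures" %in% stages) {
    .stageMsg("signatures", "signature-set statistics")
    sp <- config$signatures %||% list()
    prog <- simulateProgramSets(sim_cfg)
    res <- lapply(prog[c("gzmb", "gzmk")], intersectionPermutationTest,
                  B = sp$B %||% 1000, seed = deriveSeed(seed, "sig"))
    px <- simulateProgramExpression(prog, seed = deriveSeed(seed, "px"))
    mods <- coexpressionModules(px$expr, n_modules = 2)
    writeGeneSetsGMT(prog$gzmb, file.path(out_dir, "sets_gzmb.gmt"))
    writeGeneSetsGMT(prog$gzmk, file.path(out_dir, "sets_gzmk.gmt"))
    utils::write.table(
      data.frame(gene = names(moduleAssignments(mods)),
                 module = moduleAssignments(mods)),
      file.path(out_dir, "modules.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    jsonlite::write_json(lapply(res, function(r) list(
      observed = r@observed, null_mean = r@null_mean, null_sd = r@null_sd,
      p_empirical = r@p_empirical, p_ttest = r@p_ttest, B = r@B,
      regions = as.list(r@regions))),
      file.path(out_dir, "signatures.json"), auto_unbox = TRUE, digits = NA)
    manifest$records$signatures <- lapply(res, function(r)
      list(observed = r@observed, p_empirical = r@p_empirical))
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$timestamp <- format(Sys.time(), tz = "UTC")
  invisible(manifest)
}
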