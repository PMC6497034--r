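#' @import methods
#' @importFrom stats rnbinom rnorm runif rbinom sd cor rank hclust cutree
#'   as.dist t.test pnorm p.adjust setNames quantile var
#' @importFrom utils head combn packageVersion
NULL

#' Simulation configuration
#'
#' Parameters of the synthetic UMI-count generator. The defaults describe a
#' four-batch cord-blood-like cohort: negative-binomial counts over seven
#' discrete cell types plus a hemoglobin-high (nucleated red blood cell)
#' subpopulation at 3.92\% of cells, per-gene multiplicative batch effects,
#' ~5\% doublets, a 667-cell maturation trajectory with three gene waves and
#' library size decaying along pseudotime, and four-set signature programs of
#' sizes 116--144 sharing planted cores of 31 (GZMB-like) and 22 (GZMK-like)
#' genes.
#'
#' @slot n_batches number of batches (samples).
#' @slot cells_per_batch cells simulated per batch.
#' @slot n_genes size of the gene universe.
#' @slot n_cell_types number of discrete singlet cell types (the
#'   hemoglobin-high population is added on top).
#' @slot nb_mean_range range of per-gene baseline negative-binomial means;
#'   baselines are drawn log-uniformly in this interval.
#' @slot nb_dispersion NB size parameter \eqn{\theta}; variance is
#'   \eqn{\mu + \mu^2/\theta}.
#' @slot batch_logfc_sd SD of the per-gene, per-batch log-normal
#'   multiplicative batch effect (0 = no batch effect).
#' @slot hb_fraction expected fraction of hemoglobin-high cells.
#' @slot traj_n_cells number of cells on the maturation trajectory.
#' @slot traj_stage_genes integer(3), sizes of the early / intermediate /
#'   late gene waves.
#' @slot libsize_decay relative drop of expected total UMI from pseudotime 0
#'   to 1 (must be < 1).
#' @slot program_set_sizes integer(4), sizes of the four signature sets of a
#'   program family.
#' @slot core_sizes integer(2), planted shared-core sizes for the GZMB-like
#'   and GZMK-like program families.
#' @slot doublet_fraction expected fraction of doublet cells.
#' @slot n_doublet_pairs number of distinct parent-type pairs doublets are
#'   drawn from.
#' @slot seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @seealso [simConfig()], [simulateCohort()]
#' @export
setClass("SimConfig", representation(
  n_batches = "integer",
  cells_per_batch = "integer",
  n_genes = "integer",
  n_cell_types = "integer",
  nb_mean_range = "numeric",
  nb_dispersion = "numeric",
  batch_logfc_sd = "numeric",
  hb_fraction = "numeric",
  traj_n_cells = "integer",
  traj_stage_genes = "integer",
  libsize_decay = "numeric",
  program_set_sizes = "integer",
  core_sizes = "integer",
  doublet_fraction = "numeric",
  n_doublet_pairs = "integer",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  chkCount <- function(x, nm, len = 1L) {
    if (length(x) != len || anyNA(x) || any(x < 1L))
      return(sprintf("'%s' must be %d positive integer(s)", nm, len))
    NULL
  }
  chkProp <- function(x, nm) {
    if (length(x) != 1L || is.na(x) || x < 0 || x > 1)
      return(sprintf("'%s' must be a proportion in [0, 1]", nm))
    NULL
  }
  msgs <- c(
    chkCount(object@n_batches, "n_batches"),
    chkCount(object@cells_per_batch, "cells_per_batch"),
    chkCount(object@n_genes, "n_genes"),
    chkCount(object@n_cell_types, "n_cell_types"),
    chkCount(object@traj_n_cells, "traj_n_cells"),
    chkCount(object@traj_stage_genes, "traj_stage_genes", 3L),
    chkCount(object@program_set_sizes, "program_set_sizes", 4L),
    chkCount(object@n_doublet_pairs, "n_doublet_pairs"),
    chkProp(object@hb_fraction, "hb_fraction"),
    chkProp(object@doublet_fraction, "doublet_fraction")
  )
  if (length(object@nb_mean_range) != 2L || any(object@nb_mean_range <= 0) ||
      diff(object@nb_mean_range) < 0)
    msgs <- c(msgs, "'nb_mean_range' must be two increasing positive reals")
  if (length(object@nb_dispersion) != 1L || object@nb_dispersion <= 0)
    msgs <- c(msgs, "'nb_dispersion' must be a positive real")
  if (length(object@batch_logfc_sd) != 1L || object@batch_logfc_sd < 0)
    msgs <- c(msgs, "'batch_logfc_sd' must be a non-negative real")
  if (length(object@libsize_decay) != 1L || object@libsize_decay < 0 ||
      object@libsize_decay >= 1)
    msgs <- c(msgs, "'libsize_decay' must lie in [0, 1)")
  if (length(object@core_sizes) != 2L || any(object@core_sizes < 0))
    msgs <- c(msgs, "'core_sizes' must be two non-negative integers")
  if (all(object@core_sizes >= 0) && length(object@program_set_sizes) == 4L &&
      any(max(object@core_sizes) > min(object@program_set_sizes)))
    msgs <- c(msgs, "'core_sizes' may not exceed the smallest program set size")
  if (length(object@seed) != 1L || is.na(object@seed))
    msgs <- c(msgs, "'seed' must be a single integer")
  if (length(msgs)) msgs else TRUE
})

#' Construct a simulation configuration
#'
#' @param n_batches,cells_per_batch,n_genes,n_cell_types,nb_mean_range,nb_dispersion,batch_logfc_sd,hb_fraction,traj_n_cells,traj_stage_genes,libsize_decay,program_set_sizes,core_sizes,doublet_fraction,n_doublet_pairs,seed
#'   see the slot documentation of [SimConfig-class].
#' @return a validated `SimConfig`.
#' @examples
#' cfg <- simConfig(seed = 1L)
#' cfg
#' @export
simConfig <- function(n_batches = 4, cells_per_batch = 500, n_genes = 2000,
                      n_cell_types = 7, nb_mean_range = c(0.05, 3),
                      nb_dispersion = 2, batch_logfc_sd = 0.15,
                      hb_fraction = 0.0392, traj_n_cells = 667,
                      traj_stage_genes = c(60, 60, 60), libsize_decay = 0.6,
                      program_set_sizes = c(116, 125, 134, 144),
                      core_sizes = c(31, 22), doublet_fraction = 0.05,
                      n_doublet_pairs = 4, seed = 1) {
  new("SimConfig",
      n_batches = as.integer(n_batches),
      cells_per_batch = as.integer(cells_per_batch),
      n_genes = as.integer(n_genes),
      n_cell_types = as.integer(n_cell_types),
      nb_mean_range = as.numeric(nb_mean_range),
      nb_dispersion = as.numeric(nb_dispersion),
      batch_logfc_sd = as.numeric(batch_logfc_sd),
      hb_fraction = as.numeric(hb_fraction),
      traj_n_cells = as.integer(traj_n_cells),
      traj_stage_genes = as.integer(traj_stage_genes),
      libsize_decay = as.numeric(libsize_decay),
      program_set_sizes = as.integer(program_set_sizes),
      core_sizes = as.integer(core_sizes),
      doublet_fraction = as.numeric(doublet_fraction),
      n_doublet_pairs = as.integer(n_doublet_pairs),
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:",
      object@n_batches, "batches x", object@cells_per_batch, "cells,",
      object@n_genes, "genes,", object@n_cell_types, "cell types\n")
  cat("  NB mean range [", paste(object@nb_mean_range, collapse = ", "),
      "], dispersion ", object@nb_dispersion,
      ", batch logFC sd ", object@batch_logfc_sd, "\n", sep = "")
  cat("  hb_fraction ", object@hb_fraction,
      ", doublet_fraction ", object@doublet_fraction,
      ", seed ", object@seed, "\n", sep = "")
})

#' Alignment-score result
#'
#' Result of the k-nearest-neighbour batch-mixing score
#' \eqn{1 - (\bar x - k/N)/(k - k/N)}, clamped to [0, 1], where \eqn{\bar x}
#' is the mean number of same-batch cells among each sampled cell's k nearest
#' neighbours after subsampling every batch to the smallest batch size.
#'
#' @slot k neighbourhood size.
#' @slot N number of batches.
#' @slot x_bar mean same-batch neighbour count over sampled cells (averaged
#'   over subsampling repeats).
#' @slot score the normalized mixing score in [0, 1].
#' @slot n_sampled_per_batch cells drawn from each batch (the minimum batch
#'   size).
#' @slot repeats number of independent subsampling repeats averaged.
#' @slot seed seed used for subsampling.
#' @export
setClass("AlignmentScore", representation(
  k = "integer", N = "integer", x_bar = "numeric", score = "numeric",
  n_sampled_per_batch = "integer", repeats = "integer", seed = "integer"))

setValidity("AlignmentScore", function(object) {
  if (object@x_bar < 0 || object@x_bar > object@k)
    return("x_bar must lie in [0, k]")
  if (object@score < 0 || object@score > 1)
    return("score must lie in [0, 1]")
  TRUE
})

setMethod("show", "AlignmentScore", function(object) {
  cat(sprintf(
    "AlignmentScore: %.4f (k = %d, N = %d, x_bar = %.2f, %d cells/batch)\n",
    object@score, object@k, object@N, object@x_bar,
    object@n_sampled_per_batch))
})

#' @describeIn AlignmentScore-class the score value.
#' @param x an `AlignmentScore`.
#' @export
alignScore <- function(x) x@score

#' @describeIn AlignmentScore-class mean same-batch neighbour count.
#' @export
xBar <- function(x) x@x_bar

#' Permutation-test result
#'
#' Common container for permutation-null resampling tests: the observed
#' statistic, the null sample, the empirical p-value
#' \eqn{(1 + \#\{null \ge obs\})/(1 + B)} (or its two-sided analogue), and
#' a Student-t p-value for the deviation of the observed statistic from the
#' permutation distribution, \eqn{t = (obs - \bar{null})/sd(null)} on
#' \eqn{B - 1} degrees of freedom.
#'
#' @slot statistic name of the test statistic.
#' @slot observed observed value.
#' @slot null null sample of length `B`.
#' @slot p_empirical empirical permutation p-value.
#' @slot p_ttest Student-t p-value of the observed value's deviation from
#'   the null sample, scaled by the null SD (0 when the null sample is
#'   constant and differs from the observed value, 1 when it equals it).
#' @slot B number of permutations.
#' @slot seed seed used for shuffling.
#' @export
setClass("PermutationResult", representation(
  statistic = "character", observed = "numeric", null = "numeric",
  p_empirical = "numeric", p_ttest = "numeric", B = "integer",
  seed = "integer"))

setValidity("PermutationResult", function(object) {
  if (length(object@null) != object@B)
    return("null sample length must equal B")
  if (object@p_empirical < 0 || object@p_empirical > 1)
    return("p_empirical must lie in [0, 1]")
  TRUE
})

#' Ordering-concordance permutation test result
#'
#' @slot rho_signed signed Spearman rho of the two orderings.
#' @slot rho_abs absolute rho (trajectory orientation is arbitrary between
#'   inference methods, so significance is assessed on the magnitude).
#' @export
setClass("ConcordanceResult", contains = "PermutationResult",
         representation(rho_signed = "numeric", rho_abs = "numeric"))

setMethod("show", "ConcordanceResult", function(object) {
  cat(sprintf(
    "ConcordanceResult: rho = %.4f (|rho| = %.4f)\n  B = %d, p_empirical = %.4g, p_ttest = %.4g\n",
    object@rho_signed, object@rho_abs, object@B, object@p_empirical,
    object@p_ttest))
})

#' Multi-set intersection permutation test result
#'
#' @slot regions named integer vector of all 2^m - 1 Venn region counts.
#' @slot null_mean,null_sd summary of the null full-intersection size.
#' @export
setClass("IntersectionTestResult", contains = "PermutationResult",
         representation(regions = "integer", null_mean = "numeric",
                        null_sd = "numeric"))

setMethod("show", "IntersectionTestResult", function(object) {
  cat(sprintf(
    "IntersectionTestResult: observed full intersection = %d\n  null mean %.4f (sd %.4f, B = %d); p_empirical = %.4g, p_ttest = %.4g\n",
    as.integer(object@observed), object@null_mean, object@null_sd, object@B,
    object@p_empirical, object@p_ttest))
})

#' @describeIn PermutationResult-class the observed statistic.
#' @param x a `PermutationResult`.
#' @export
observedStat <- function(x) x@observed

#' @describeIn PermutationResult-class the null sample.
#' @export
nullSample <- function(x) x@null

#' @describeIn PermutationResult-class empirical permutation p-value.
#' @export
pEmpirical <- function(x) x@p_empirical

#' @describeIn PermutationResult-class one-sample t-test p-value.
#' @export
pTTest <- function(x) x@p_ttest

#' Named gene-set collection over a common universe
#'
#' @slot sets named list of character vectors, each a subset of `universe`.
#' @slot universe the gene universe.
#' @export
setClass("GeneSetCollection", representation(
  sets = "list", universe = "character"))

setValidity("GeneSetCollection", function(object) {
  if (length(object@sets) < 1L) return("at least one set required")
  if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
    return("sets must be uniquely named")
  if (anyDuplicated(object@universe)) return("universe ids must be unique")
  for (nm in names(object@sets)) {
    s <- object@sets[[nm]]
    if (length(s) < 1L) return(sprintf("set '%s' is empty", nm))
    if (anyDuplicated(s)) return(sprintf("set '%s' has duplicate genes", nm))
    if (!all(s %in% object@universe))
      return(sprintf("set '%s' contains genes outside the universe", nm))
  }
  TRUE
})

#' Construct a gene-set collection
#'
#' @param sets named list of character gene vectors.
#' @param universe gene universe; defaults to the union of the sets.
#' @return a validated `GeneSetCollection`.
#' @export
geneSetCollection <- function(sets, universe = NULL) {
  if (is.null(universe)) universe <- unique(unlist(sets, use.names = FALSE))
  new("GeneSetCollection", sets = lapply(sets, as.character),
      universe = as.character(universe))
}

setMethod("show", "GeneSetCollection", function(object) {
  cat(sprintf("GeneSetCollection: %d sets over %d genes\n",
              length(object@sets), length(object@universe)))
  sz <- vapply(object@sets, length, integer(1))
  cat(" ", paste(sprintf("%s (%d)", names(sz), sz), collapse = ", "), "\n")
})

#' @describeIn GeneSetCollection-class the named list of sets.
#' @param x a `GeneSetCollection`.
#' @export
geneSets <- function(x) x@sets

#' @describeIn GeneSetCollection-class the gene universe.
#' @export
geneUniverse <- function(x) x@universe

#' Gene-gene co-expression modules
#'
#' @slot cor symmetric gene-gene Pearson correlation matrix with unit
#'   diagonal.
#' @slot modules named integer module assignment, one module per gene.
#' @slot n_modules number of modules the dendrogram was cut into.
#' @slot zero_variance genes with zero variance across the selected cells;
#'   their correlations are set to 0 by convention.
#' @slot linkage agglomeration method used on distance 1 - r.
#' @export
setClass("CorrelationModules", representation(
  cor = "matrix", modules = "integer", n_modules = "integer",
  zero_variance = "character", linkage = "character"))

setMethod("show", "CorrelationModules", function(object) {
  cat(sprintf("CorrelationModules: %d genes in %d modules (%s linkage)\n",
              nrow(object@cor), object@n_modules, object@linkage))
  print(table(object@modules))
})

#' @describeIn CorrelationModules-class module assignment per gene.
#' @param x a `CorrelationModules`.
#' @export
moduleAssignments <- function(x) x@modules

#' @describeIn CorrelationModules-class the correlation matrix.
#' @export
corMatrix <- function(x) x@cor
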