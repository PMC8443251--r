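#' @import methods
#' @importFrom stats quantile median density rnbinom rlnorm rpois rbeta runif
#'   rbinom rnorm rgamma sd var prcomp wilcox.test p.adjust pbinom t.test
#'   setNames qbeta binom.test
#' @importFrom utils head write.csv read.csv write.table read.table
#' @importFrom graphics hist
#' @importFrom tools md5sum
NULL

#' Configuration of the synthetic V-SVZ dataset generator
#'
#' Parameters of the generative model used throughout the package to
#' validate the analysis stages: a B (quiescent/activated) -> C ->
#' A (dividing/migrating) neurogenic lineage crossed with persistent dorsal
#' and ventral gene programs, negative-binomial counts with cell-specific
#' depth, mitochondrial content, sample barcoding with doublets, and
#' region-dissected nucleus samples.
#'
#' @slot seed Integer seed for all randomness in generation.
#' @slot n_genes Total number of genes in the simulated universe.
#' @slot stage_sizes Named integer vector of cells per lineage stage
#'   (\code{B_quiescent}, \code{B_active}, \code{C}, \code{A_dividing},
#'   \code{A_migrating}).
#' @slot region_fractions Named numeric vector over \code{dorsal} and
#'   \code{ventral}, summing to 1.
#' @slot program_genes Named integer vector of genes per program:
#'   \code{stage} (per lineage stage), \code{dorsal}, \code{ventral},
#'   \code{mito}, \code{s_phase}, \code{g2m}.
#' @slot effect_size Multiplicative fold-change of program genes in the
#'   cells expressing the program (dimensionless, >= 1).
#' @slot nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @slot depth_lognormal Numeric length-2 vector \code{(meanlog, sdlog)} of
#'   the log library-size distribution.
#' @slot doublet_rate Fraction of emitted cells that are doublets.
#' @slot n_barcodes Number of sample barcodes (= number of multiplexed
#'   samples).
#' @slot barcode_signal_to_noise Ratio of on-target to off-target expected
#'   barcode counts (> 1).
#' @slot nucleus_region_depth_factor Named numeric depth multiplier per
#'   region for the dissected nucleus samples.
#' @slot nucleus_dorsal_cell_fraction Fraction of dorsal cells retained in
#'   nucleus samples (dorsal dissections recover fewer nuclei).
#' @export
setClass("SimConfig", representation(
  seed = "integer",
  n_genes = "integer",
  stage_sizes = "integer",
  region_fractions = "numeric",
  program_genes = "integer",
  effect_size = "numeric",
  nb_dispersion = "numeric",
  depth_lognormal = "numeric",
  doublet_rate = "numeric",
  n_barcodes = "integer",
  barcode_signal_to_noise = "numeric",
  nucleus_region_depth_factor = "numeric",
  nucleus_dorsal_cell_fraction = "numeric"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  stages <- c("B_quiescent", "B_active", "C", "A_dividing", "A_migrating")
  if (!all(stages %in% names(object@stage_sizes)))
    msg <- c(msg, "stage_sizes must name all five lineage stages")
  if (any(object@stage_sizes < 0))
    msg <- c(msg, "stage_sizes must all be >= 0")
  if (!all(c("dorsal", "ventral") %in% names(object@region_fractions)) ||
      abs(sum(object@region_fractions) - 1) > 1e-8)
    msg <- c(msg, "region_fractions must cover dorsal/ventral and sum to 1")
  progs <- c("stage", "dorsal", "ventral", "mito", "s_phase", "g2m")
  if (!all(progs %in% names(object@program_genes)))
    msg <- c(msg, "program_genes must name stage, dorsal, ventral, mito, s_phase, g2m")
  n_prog <- 5L * object@program_genes[["stage"]] +
    sum(object@program_genes[c("dorsal", "ventral", "mito", "s_phase", "g2m")])
  if (n_prog > object@n_genes)
    msg <- c(msg, "program gene sets exceed the gene universe (must be disjoint)")
  if (object@effect_size < 1) msg <- c(msg, "effect_size must be >= 1")
  if (object@nb_dispersion <= 0) msg <- c(msg, "nb_dispersion must be > 0")
  if (object@doublet_rate < 0 || object@doublet_rate > 1)
    msg <- c(msg, "doublet_rate must lie in [0, 1]")
  if (object@barcode_signal_to_noise <= 1)
    msg <- c(msg, "barcode_signal_to_noise must be > 1")
  if (length(msg)) msg else TRUE
})

#' Cell-level quality-control report
#'
#' Itemized record of a [qcFilter()] run: how many cells entered, how many
#' each rule removed (a cell failing several rules is attributed to the
#' first failing rule in the fixed order UMI, genes, mito), how many were
#' retained, and the doublet tally from demultiplexing.
#'
#' @slot n_input Number of cells before filtering.
#' @slot n_removed_by_rule Named integer vector (\code{umi}, \code{genes},
#'   \code{mito}) of removals attributed per rule.
#' @slot n_retained Cells surviving all rules.
#' @slot doublet_count Doublets flagged by barcode classification (0 until
#'   demultiplexing results are folded in).
#' @export
setClass("QcReport", representation(
  n_input = "integer",
  n_removed_by_rule = "integer",
  n_retained = "integer",
  doublet_count = "integer"
))

setValidity("QcReport", function(object) {
  if (object@n_input != object@n_retained + sum(object@n_removed_by_rule))
    return("n_input must equal n_retained plus total removed")
  TRUE
})

#' Mutual-nearest-neighbor anchors between reference and query cells
#'
#' Anchor pairs found in a shared low-dimensional embedding, with a
#' neighborhood-overlap score rescaled to [0, 1].
#'
#' @slot ref Integer indices of reference cells (one per anchor).
#' @slot query Integer indices of query cells (one per anchor).
#' @slot score Numeric anchor scores in [0, 1].
#' @slot ref_embedding,query_embedding Shared-embedding coordinates
#'   (cells x dims) for the two datasets.
#' @export
setClass("AnchorSet", representation(
  ref = "integer",
  query = "integer",
  score = "numeric",
  ref_embedding = "matrix",
  query_embedding = "matrix"
))

setValidity("AnchorSet", function(object) {
  if (length(object@ref) != length(object@query) ||
      length(object@ref) != length(object@score))
    return("ref, query and score must have one entry per anchor")
  if (length(object@score) && (min(object@score) < 0 || max(object@score) > 1))
    return("anchor scores must lie in [0, 1]")
  TRUE
})

#' Per-cell predicted regional identity
#'
#' Class scores over the reference regions for each query cell (rows sum to
#' 1), the net dorsal - ventral score, and the argmax class.
#'
#' @slot scores Numeric matrix, query cells x reference classes; rows sum
#'   to 1.
#' @slot net_score Numeric vector, \code{Dorsal} score minus \code{Ventral}
#'   score per cell, in [-1, 1].
#' @slot predicted_class Character vector of argmax classes (ties broken
#'   toward Dorsal, then lexicographically).
#' @export
setClass("PredictedIdentity", representation(
  scores = "matrix",
  net_score = "numeric",
  predicted_class = "character"
))

setValidity("PredictedIdentity", function(object) {
  if (nrow(object@scores) != length(object@net_score) ||
      nrow(object@scores) != length(object@predicted_class))
    return("scores, net_score and predicted_class must agree in length")
  if (nrow(object@scores) &&
      max(abs(rowSums(object@scores) - 1)) > 1e-6)
    return("class scores must sum to 1 per cell")
  TRUE
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@n_genes, "genes,",
      sum(object@stage_sizes), "cells across",
      length(object@stage_sizes), "stages\n")
  cat("  effect_size:", object@effect_size,
      " dispersion:", object@nb_dispersion,
      " doublet_rate:", object@doublet_rate, "\n")
  cat("  regions:", paste(sprintf("%s=%.2f", names(object@region_fractions),
                                  object@region_fractions), collapse = ", "), "\n")
})

setMethod("show", "QcReport", function(object) {
  cat(qcSummary(object), sep = "\n")
})

setMethod("show", "AnchorSet", function(object) {
  cat("AnchorSet with", length(object@ref), "anchors in",
      ncol(object@ref_embedding), "shared dimensions\n")
})

setMethod("show", "PredictedIdentity", function(object) {
  cat("PredictedIdentity for", nrow(object@scores), "query cells over classes:",
      paste(colnames(object@scores), collapse = ", "), "\n")
  if (nrow(object@scores))
    cat("  net score range:",
        sprintf("[%.3f, %.3f]", min(object@net_score), max(object@net_score)), "\n")
})

#' @rdname AnchorSet-class
#' @param x An \code{AnchorSet}.
#' @return \code{anchorScores} returns the numeric score vector;
#'   \code{anchorPairs} a two-column matrix of (ref, query) indices.
#' @export
anchorScores <- function(x) x@score

#' @rdname AnchorSet-class
#' @export
anchorPairs <- function(x) cbind(ref = x@ref, query = x@query)

#' @rdname PredictedIdentity-class
#' @param x A \code{PredictedIdentity}.
#' @return \code{classScores} the cells x classes score matrix;
#'   \code{netScore} the dorsal minus ventral vector; \code{predictedClass}
#'   the argmax class per cell.
#' @export
classScores <- function(x) x@scores

#' @rdname PredictedIdentity-class
#' @export
netScore <- function(x) x@net_score

#' @rdname PredictedIdentity-class
#' @export
predictedClass <- function(x) x@predicted_class
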