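#' Log-normalize counts
#'
#' Per-cell depth normalization to a fixed scale factor followed by a
#' natural-log transform: \code{log(pseudocount + scale * count / total)}.
#' Cells with proportional raw profiles map to identical normalized
#' profiles.
#'
#' @param counts Genes x cells counts (matrix, sparse \code{Matrix} or
#'   \code{SingleCellExperiment}).
#' @param scale Scale factor (default 10000).
#' @param pseudocount Added inside the log (default 1).
#' @return Genes x cells dense numeric matrix; if the input was a
#'   \code{SingleCellExperiment}, the object with a \code{logcounts} assay.
#' @export
logNormalize <- function(counts, scale = 10000, pseudocount = 1) {
  sce <- NULL
  if (methods::is(counts, "SummarizedExperiment")) {
    sce <- counts
    counts <- SummarizedExperiment::assay(counts, "counts")
  }
  tot <- Matrix::colSums(counts)
  if (any(tot == 0)) stop("zero-total cell encountered; run qcFilter first")
  norm <- log(pseudocount + sweep(as.matrix(counts), 2, scale / tot, "*"))
  if (!is.null(sce)) {
    SummarizedExperiment::assay(sce, "logcounts") <- norm
    return(sce)
  }
  norm
}

#' Centered log-ratio normalization for antibody-tag counts
#'
#' Per cell, \code{value_i = log1p(x_i) - mean_j log1p(x_j)} across tags.
#'
#' @param tag_counts Tags x cells non-negative count matrix.
#' @return Tags x cells CLR matrix.
#' @export
clrNormalize <- function(tag_counts) {
  tag_counts <- as.matrix(tag_counts)
  if (any(tag_counts < 0)) stop("tag counts must be non-negative")
  lg <- log1p(tag_counts)
  sweep(lg, 2, colMeans(lg), "-")
}

#' Select highly variable genes
#'
#' Ranks genes by dispersion (variance / mean of normalized expression)
#' standardized within mean-expression bins, the usual dispersion-based
#' criterion.
#'
#' @param expr Genes x cells normalized expression.
#' @param n Number of genes to keep (default 2000; capped at the universe).
#' @param n_bins Mean-expression bins for standardization (default 20).
#' @return Character vector of gene names, most variable first.
#' @export
selectHVG <- function(expr, n = 2000, n_bins = 20) {
  mu <- rowMeans(expr)
  v <- apply(expr, 1, var)
  disp <- ifelse(mu > 0, v / mu, 0)
  bins <- cut(rank(mu, ties.method = "first"), breaks = n_bins, labels = FALSE)
  z <- disp
  for (b in unique(bins)) {
    i <- bins == b
    s <- sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  names(sort(z, decreasing = TRUE))[seq_len(min(n, nrow(expr)))]
}

#' Principal-component embedding
#'
#' PCA of gene-standardized expression (each gene centered and scaled to
#' unit variance; zero-variance genes dropped). Component signs are fixed
#' by making the largest-magnitude gene loading positive, so the embedding
#' is deterministic.
#'
#' @param expr Genes x cells normalized expression.
#' @param n_components Number of components to retain.
#' @param features Optional gene subset (e.g. from [selectHVG()]).
#' @return List with \code{coords} (cells x k), \code{loadings}
#'   (genes x k), \code{var_explained} (fraction per component, decreasing).
#' @export
embedCells <- function(expr, n_components = 50, features = NULL) {
  if (!is.null(features)) expr <- expr[features, , drop = FALSE]
  keep <- apply(expr, 1, sd) > 0
  x <- t(scale(t(expr[keep, , drop = FALSE])))   # genes standardized
  max_k <- min(dim(x)) - 1L
  if (n_components > max_k) {
    warning("n_components exceeds rank; truncated to ", max_k)
    n_components <- max_k
  }
  pc <- prcomp(t(x), center = FALSE, scale. = FALSE, rank. = n_components)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(k) {
    l <- pc$rotation[, k]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  coords <- sweep(pc$x, 2, flip, "*")
  loadings <- sweep(pc$rotation, 2, flip, "*")
  total_var <- sum(apply(t(x), 2, var))
  list(coords = coords, loadings = loadings,
       var_explained = pc$sdev[seq_len(n_components)]^2 / total_var)
}

## shared-nearest-neighbor graph with Jaccard edge weights
.snn_graph <- function(coords, k_neighbors) {
  n <- nrow(coords)
  if (k_neighbors >= n) stop("k_neighbors must be smaller than the number of cells")
  nn <- .knn_index(coords, coords, k_neighbors, drop_self = TRUE)
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), each = ncol(nn)),
                              j = as.vector(t(nn)), x = 1, dims = c(n, n))
  shared <- adj %*% Matrix::t(adj)  # counts of shared neighbours
  shared <- methods::as(shared, "TsparseMatrix")
  i <- shared@i + 1L; j <- shared@j + 1L; s <- shared@x
  keep <- i < j & s > 0
  jac <- s[keep] / (2 * k_neighbors - s[keep])
  igraph::graph_from_data_frame(
    data.frame(from = i[keep], to = j[keep], weight = jac),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
}

#' Leiden clustering on a shared-nearest-neighbor graph
#'
#' Builds a Jaccard-weighted SNN graph on the embedding and partitions it
#' with the Leiden algorithm (modularity objective). Labels are integers
#' \code{0..K-1} ordered by decreasing cluster size.
#'
#' @param emb Cells x k embedding matrix (or the list from [embedCells()]).
#' @param resolution Modularity resolution; higher values yield more, and
#'   never fewer, communities on a fixed graph.
#' @param k_neighbors Neighbors for the SNN graph (default 20).
#' @param seed Integer seed (Leiden refinement is randomized).
#' @return Integer vector of cluster labels.
#' @export
clusterCells <- function(emb, resolution = 1.0, k_neighbors = 20, seed = 1L) {
  coords <- if (is.list(emb)) emb$coords else as.matrix(emb)
  g <- .snn_graph(coords, k_neighbors)
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 5)
  memb <- igraph::membership(cl)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes) - 1L, names(sizes))
  unname(relabel[as.character(memb)])
}

#' Cell-cycle phase scoring
#'
#' Module-score phase assignment: genes are binned by their mean
#' expression across cells (\code{n_bins} bins); for every program gene,
#' \code{n_ctrl} control genes are drawn from its bin; a cell's program
#' score is its mean program-gene expression minus its mean control-gene
#' expression. Phase is \code{G1} when both scores are <= 0, otherwise the
#' argmax of the S and G2M scores, with the exact tie going to S.
#'
#' @param expr Genes x cells normalized expression.
#' @param s_genes,g2m_genes Phase program gene sets.
#' @param n_bins Expression bins for control matching (default 25).
#' @param n_ctrl Control genes per program gene (default 50).
#' @param seed Integer seed for control sampling.
#' @return \code{data.frame} with \code{s_score}, \code{g2m_score},
#'   \code{phase} per cell.
#' @export
cellCycleScore <- function(expr, s_genes, g2m_genes, n_bins = 25,
                           n_ctrl = 50, seed = 1L) {
  score_one <- function(genes) {
    genes <- intersect(genes, rownames(expr))
    if (!length(genes)) stop("program gene set does not intersect the universe")
    mu <- rowMeans(expr)
    bins <- cut(rank(mu, ties.method = "first"),
                breaks = min(n_bins, nrow(expr)), labels = FALSE)
    non_prog <- setdiff(rownames(expr), genes)
    ctrl <- unlist(lapply(genes, function(g) {
      pool <- setdiff(rownames(expr)[bins == bins[match(g, rownames(expr))]],
                      genes)
      if (!length(pool)) {
        ## bin holds only program genes: fall back to the non-program genes
        ## closest in mean expression
        pool <- non_prog[order(abs(mu[non_prog] -
                                     mu[match(g, rownames(expr))]))][
                                       seq_len(min(n_ctrl, length(non_prog)))]
      }
      sample(pool, min(n_ctrl, length(pool)), replace = FALSE)
    }))
    ctrl <- unique(ctrl)
    if (!length(ctrl)) stop("no control genes available for module scoring")
    colMeans(expr[genes, , drop = FALSE]) -
      colMeans(expr[ctrl, , drop = FALSE])
  }
  set.seed(seed)
  s <- score_one(s_genes)
  g2m <- score_one(g2m_genes)
  phase <- ifelse(s <= 0 & g2m <= 0, "G1", ifelse(s >= g2m, "S", "G2M"))
  data.frame(s_score = s, g2m_score = g2m, phase = phase,
             row.names = colnames(expr), stringsAsFactors = FALSE)
}

#' Phase-fraction summary
#'
#' Formats the share of cells in a phase as a truncated one-decimal
#' percentage (691 S-phase cells among 992 print as \code{"69.6\%"}).
#'
#' @param phases Character vector of phase labels (or the data.frame from
#'   [cellCycleScore()]).
#' @param phase Phase to report (default \code{"S"}).
#' @return Character scalar like \code{"691/992, 69.6\%"}.
#' @export
phaseSummary <- function(phases, phase = "S") {
  if (is.data.frame(phases)) phases <- phases$phase
  k <- sum(phases == phase)
  n <- length(phases)
  sprintf("%d/%d, %s", k, n, percentTruncated(k, n))
}

#' Center genes within batches
#'
#' Minimal cross-batch harmonization: subtracts the per-batch gene mean so
#' that batch-specific offsets do not dominate a joint embedding.
#'
#' @param expr Genes x cells normalized expression.
#' @param batch Factor of batch labels, one per cell.
#' @return Centered matrix of the same shape.
#' @export
centerByBatch <- function(expr, batch) {
  batch <- as.factor(batch)
  out <- expr
  for (b in levels(batch)) {
    i <- batch == b
    out[, i] <- expr[, i, drop = FALSE] - rowMeans(expr[, i, drop = FALSE])
  }
  out
}
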