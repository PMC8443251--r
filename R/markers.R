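#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' Per-gene two-sided Wilcoxon rank-sum test of group 1 versus group 2 on
#' normalized expression: exact when the combined group size is at most 25
#' and the gene has no ties, otherwise the normal approximation with tie
#' correction and continuity correction. The log fold change is the
#' natural log of the ratio of back-transformed group means,
#' \code{log((mean(expm1(x1)) + eps) / (mean(expm1(x2)) + eps))} with
#' \code{eps = 1e-9}. P-values are Benjamini-Hochberg adjusted across all
#' tested genes; rows are sorted by ascending adjusted p, then descending
#' absolute log fold change.
#'
#' @param expr Genes x cells normalized (log) expression.
#' @param group1,group2 Disjoint cell identifier (or index) sets, each of
#'   size >= 3.
#' @param counts Optional genes x cells raw counts used for the
#'   fraction-expressing columns; by default "expressed" means normalized
#'   value > 0, equivalent to raw count > 0 under log1p normalization.
#' @return \code{data.frame} (one row per gene): \code{gene},
#'   \code{log_fc}, \code{p}, \code{p_adj}, \code{pct_1}, \code{pct_2},
#'   \code{mean_1}, \code{mean_2}.
#' @examples
#' m <- matrix(rnorm(200, 2), 10, 20,
#'             dimnames = list(paste0("g", 1:10), paste0("c", 1:20)))
#' de <- wilcoxonDE(m, paste0("c", 1:10), paste0("c", 11:20))
#' @export
wilcoxonDE <- function(expr, group1, group2, counts = NULL) {
  i1 <- if (is.character(group1)) match(group1, colnames(expr)) else group1
  i2 <- if (is.character(group2)) match(group2, colnames(expr)) else group2
  if (anyNA(i1) || anyNA(i2)) stop("unknown cells in group definitions")
  if (length(intersect(i1, i2))) stop("groups must be disjoint")
  if (length(i1) < 3 || length(i2) < 3) stop("each group needs >= 3 cells")
  x1 <- expr[, i1, drop = FALSE]
  x2 <- expr[, i2, drop = FALSE]
  detect1 <- if (is.null(counts)) x1 > 0 else counts[, i1, drop = FALSE] > 0
  detect2 <- if (is.null(counts)) x2 > 0 else counts[, i2, drop = FALSE] > 0
  eps <- 1e-9
  n_small <- (length(i1) + length(i2)) <= 25

  res <- vapply(seq_len(nrow(expr)), function(g) {
    a <- x1[g, ]; b <- x2[g, ]
    if (sd(c(a, b)) == 0) {
      p <- 1
    } else {
      ties <- anyDuplicated(c(a, b)) > 0
      p <- suppressWarnings(
        wilcox.test(a, b, exact = n_small && !ties, correct = TRUE)$p.value)
    }
    c(p = p,
      mean_1 = mean(a), mean_2 = mean(b),
      pct_1 = mean(detect1[g, ]), pct_2 = mean(detect2[g, ]),
      log_fc = log((mean(expm1(a)) + eps) / (mean(expm1(b)) + eps)))
  }, numeric(6))

  de <- data.frame(gene = rownames(expr), t(res), stringsAsFactors = FALSE)
  de$p_adj <- p.adjust(de$p, method = "BH")
  de <- de[order(de$p_adj, -abs(de$log_fc)), ]
  rownames(de) <- NULL
  de[, c("gene", "log_fc", "p", "p_adj", "pct_1", "pct_2", "mean_1", "mean_2")]
}

#' One-vs-rest marker tables for every cluster
#'
#' Runs [wilcoxonDE()] for each cluster against all other cells and keeps
#' only positively enriched genes (\code{log_fc > 0}) as markers.
#' Singleton clusters are skipped with a warning.
#'
#' @param expr Genes x cells normalized expression.
#' @param labels Cluster labels, one per cell.
#' @param ... Passed to [wilcoxonDE()].
#' @return Named list of marker \code{data.frame}s, one per cluster.
#' @export
findAllMarkers <- function(expr, labels, ...) {
  labels <- as.character(labels)
  cl <- unique(labels)
  if (length(cl) < 2) stop("need at least two clusters")
  out <- list()
  for (k in sort(cl)) {
    in_k <- which(labels == k)
    if (length(in_k) < 3) {
      warning("cluster ", k, " has fewer than 3 cells; skipped")
      next
    }
    de <- wilcoxonDE(expr, in_k, which(labels != k), ...)
    out[[k]] <- de[de$log_fc > 0, , drop = FALSE]
  }
  out
}

#' Candidate-marker filter
#'
#' Restricts a DE table to significantly upregulated genes expressed in no
#' more than \code{max_other_frac} of the cells of the other group:
#' \code{p_adj < alpha}, \code{log_fc > 0}, \code{pct_2 <= max_other_frac}.
#' Input order is preserved.
#'
#' @param de A [wilcoxonDE()] table.
#' @param alpha Adjusted-p significance threshold (default 0.05).
#' @param max_other_frac Maximum fraction expressing in the other group
#'   (default 0.40).
#' @return Character vector of gene names.
#' @export
candidateMarkers <- function(de, alpha = 0.05, max_other_frac = 0.40) {
  de$gene[de$p_adj < alpha & de$log_fc > 0 & de$pct_2 <= max_other_frac]
}

#' Merge clusters under a new label
#'
#' @param labels Cluster labels, one per cell.
#' @param to_merge Labels to combine (all must exist).
#' @param new_name Replacement label (default: members joined with
#'   \code{"+"}, e.g. \code{"5+22"}).
#' @return Relabeled vector; all other labels unchanged.
#' @export
mergeClusters <- function(labels, to_merge, new_name = NULL) {
  labels <- as.character(labels)
  to_merge <- as.character(to_merge)
  missing <- setdiff(to_merge, labels)
  if (length(missing)) stop("unknown cluster(s): ", paste(missing, collapse = ", "))
  if (is.null(new_name)) new_name <- paste(to_merge, collapse = "+")
  labels[labels %in% to_merge] <- new_name
  labels
}

#' Top-n markers from a sorted DE table
#'
#' @param de A [wilcoxonDE()] table (already sorted by adjusted p).
#' @param n Number of genes (default 10).
#' @return First \code{n} gene names; all of them, with a warning, if the
#'   table is shorter.
#' @export
topMarkers <- function(de, n = 10) {
  if (n > nrow(de)) {
    if (n > 0) warning("requested ", n, " markers but table has ", nrow(de))
    n <- nrow(de)
  }
  head(de$gene, n)
}

#' Fraction of cells expressing a gene, per cluster
#'
#' "Expressed" means raw count > 0.
#'
#' @param counts Genes x cells raw counts.
#' @param labels Cluster labels, one per cell.
#' @param gene Gene name.
#' @return Named numeric vector of fractions per cluster.
#' @export
expressionFractions <- function(counts, labels, gene) {
  if (!gene %in% rownames(counts)) stop("unknown gene: ", gene)
  pos <- as.vector(counts[gene, ] > 0)
  vapply(split(pos, as.character(labels)), mean, numeric(1))
}
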