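#' Rank-based gene-set activity (area under the recovery curve)
#'
#' For each cell, genes are ranked by descending expression, ties broken
#' by one fixed seeded random permutation of the gene universe (shared
#' across cells, so identical profiles score identically). The recovery
#' curve R(k) counts set members among the top k ranks for
#' k = 1..T, T = \code{ceiling(top_frac * n_genes)}; the score is the area
#' sum of R(k) over k <= T divided by the maximum area attainable for the
#' set size and T, giving a value in [0, 1]. The score depends only on
#' within-cell expression ranks, so it is invariant to depth and to any
#' strictly monotone transform.
#'
#' @param expr Genes x cells expression matrix.
#' @param set Character vector of gene names (must intersect the
#'   universe).
#' @param top_frac Fraction of top-ranked genes considered (default 0.05).
#' @param seed Seed for the tie-breaking permutation.
#' @return List with \code{auc} (per-cell scores) and
#'   \code{threshold_rank} (T).
#' @examples
#' m <- matrix(rexp(2000), 100, 20,
#'             dimnames = list(paste0("g", 1:100), paste0("c", 1:20)))
#' aucScore(m, paste0("g", 1:10), top_frac = 0.1)$auc
#' @export
aucScore <- function(expr, set, top_frac = 0.05, seed = 1L) {
  if (top_frac <= 0 || top_frac > 1) stop("top_frac must lie in (0, 1]")
  set <- intersect(set, rownames(expr))
  if (!length(set)) stop("gene set does not intersect the expression universe")
  n_genes <- nrow(expr)
  T_rank <- as.integer(ceiling(top_frac * n_genes))
  set.seed(seed)
  tiebreak <- sample(n_genes)
  in_set <- rownames(expr) %in% set
  max_area <- sum(pmin(seq_len(T_rank), length(set)))
  auc <- vapply(seq_len(ncol(expr)), function(j) {
    ord <- order(-expr[, j], tiebreak)
    hits <- in_set[ord[seq_len(T_rank)]]
    sum(cumsum(hits)) / max_area
  }, numeric(1))
  names(auc) <- colnames(expr)
  list(auc = auc, threshold_rank = T_rank)
}

#' Min-max normalization to [0, 1]
#'
#' \code{(x - min) / (max - min)}; a zero-range input maps to all zeros
#' (documented degenerate rule).
#'
#' @param scores Numeric vector (non-empty).
#' @return Numeric vector in [0, 1].
#' @export
minmaxNormalize <- function(scores) {
  stopifnot(length(scores) > 0)
  rng <- range(scores)
  if (diff(rng) == 0) return(rep(0, length(scores)))
  (scores - rng[1]) / diff(rng)
}

#' High-Score lineage selection by composite-score quartiles
#'
#' Subtracts the (min-max normalized) ventral score from the dorsal score
#' per cell; cells at or above the third quartile of the difference are
#' \code{HighDorsal}, at or below the first quartile \code{HighVentral},
#' the rest \code{neither}. Quartiles use linear interpolation; boundary
#' ties are included, so selected fractions can exceed 25\% under mass
#' ties. A zero-range difference yields \code{neither} for every cell.
#'
#' @param dorsal,ventral Normalized score vectors aligned to the same
#'   cells (>= 4 cells).
#' @return Character vector over \code{HighDorsal}, \code{HighVentral},
#'   \code{neither}.
#' @export
highScoreSelection <- function(dorsal, ventral) {
  stopifnot(length(dorsal) == length(ventral))
  if (length(dorsal) < 4) stop("need at least 4 cells for quartile selection")
  d <- dorsal - ventral
  if (diff(range(d)) == 0) return(rep("neither", length(d)))
  q1 <- .pctl(d, 25); q3 <- .pctl(d, 75)
  out <- rep("neither", length(d))
  out[d >= q3] <- "HighDorsal"
  out[d <= q1] <- "HighVentral"
  names(out) <- names(d)
  out
}

#' Lineage signature by marker intersection
#'
#' Genes shared between the candidate markers of matched-side B and A
#' clusters: markers expressed persistently along one regional lineage.
#' Order follows the B-cell marker list.
#'
#' @param markers_B,markers_A Candidate-marker gene lists.
#' @return Character vector (possibly empty).
#' @export
lineageSignature <- function(markers_B, markers_A) {
  markers_B[markers_B %in% markers_A]
}

#' Binomial over-representation test for gene sets
#'
#' For each set, tests whether the query hits it more often than expected
#' by chance: the one-sided upper tail P(X >= k) with
#' X ~ Binomial(|query|, |set|/|background|) and k the observed overlap.
#' A hypergeometric alternative (sampling without replacement) is also
#' available. P-values are Benjamini-Hochberg adjusted across sets.
#'
#' @param query Gene list (must be contained in \code{background}).
#' @param sets Named list of gene sets.
#' @param background Gene universe.
#' @param fdr Significance threshold on adjusted p (default 0.05).
#' @param test \code{"binomial"} (default) or \code{"hypergeometric"}.
#' @return \code{data.frame}: \code{set}, \code{k} (overlap),
#'   \code{expected}, \code{p}, \code{p_adj}, \code{significant}.
#' @export
oraEnrichment <- function(query, sets, background, fdr = 0.05,
                          test = c("binomial", "hypergeometric")) {
  test <- match.arg(test)
  if (!length(background)) stop("empty background universe")
  extra <- setdiff(query, background)
  if (length(extra)) stop("query genes outside background: ",
                          paste(head(extra), collapse = ", "))
  n <- length(query)
  res <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], background)
    k <- length(intersect(query, s))
    q <- length(s) / length(background)
    p <- if (test == "binomial") {
      pbinom(k - 1, n, q, lower.tail = FALSE)
    } else {
      stats::phyper(k - 1, length(s), length(background) - length(s), n,
                    lower.tail = FALSE)
    }
    data.frame(set = nm, k = k, expected = n * q, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < fdr
  out[order(out$p_adj, out$p), ]
}
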