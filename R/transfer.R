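#' Label-transfer configuration
#'
#' @param n_dims Shared-embedding dimensions (default 30).
#' @param k_anchor Neighbors per direction for mutual-nearest-neighbor
#'   anchor search (default 5).
#' @param k_weight Anchors weighted per query cell (default 50).
#' @param k_filter Neighborhood size for anchor scoring (default 200).
#' @param nfeature_low_pct,nfeature_high_pct Genes-per-cell percentile band
#'   for reference downsampling (defaults 25 and 75).
#' @param method Shared embedding: \code{"cca"} (default) or
#'   \code{"pca-project"} (reference PCA with query projection).
#' @param seed Integer seed.
#' @return Named list of class \code{transfer_config}.
#' @export
transferConfig <- function(n_dims = 30, k_anchor = 5, k_weight = 50,
                           k_filter = 200, nfeature_low_pct = 25,
                           nfeature_high_pct = 75,
                           method = c("cca", "pca-project"), seed = 1L) {
  stopifnot(k_anchor <= k_filter, nfeature_low_pct < nfeature_high_pct)
  structure(list(n_dims = n_dims, k_anchor = k_anchor, k_weight = k_weight,
                 k_filter = k_filter, nfeature_low_pct = nfeature_low_pct,
                 nfeature_high_pct = nfeature_high_pct,
                 method = match.arg(method), seed = as.integer(seed)),
            class = "transfer_config")
}

#' Balanced downsampling of the regional reference
#'
#' Within each region, candidate cells are restricted to the inclusive
#' genes-per-cell percentile band (percentiles computed per region); the
#' common sample size is the minimum candidate count over regions, and
#' that many cells are drawn uniformly without replacement from each
#' region. This keeps the region with the most nuclei from dominating the
#' prediction scores. Anterior and posterior dissections of a side should
#' be combined into \code{Dorsal} / \code{Ventral} before calling (see
#' [combineDissections()]).
#'
#' @param region_labels Region label per reference cell.
#' @param genes_per_cell Detected genes per reference cell.
#' @param config A [transferConfig()].
#' @return Integer indices of the selected balanced reference cells.
#' @export
downsampleReference <- function(region_labels, genes_per_cell,
                                config = transferConfig()) {
  region_labels <- as.character(region_labels)
  regions <- unique(region_labels)
  if (length(regions) < 2) stop("need at least two regions")
  cand <- lapply(regions, function(r) {
    i <- which(region_labels == r)
    g <- genes_per_cell[i]
    lo <- .pctl(g, config$nfeature_low_pct)
    hi <- .pctl(g, config$nfeature_high_pct)
    i[g >= lo & g <= hi]
  })
  names(cand) <- regions
  empty <- regions[lengths(cand) == 0]
  if (length(empty)) stop("region(s) with zero candidates: ",
                          paste(empty, collapse = ", "))
  n <- min(lengths(cand))
  set.seed(config$seed)
  sort(unlist(lapply(cand, function(i) sample(i, n)), use.names = FALSE))
}

#' Combine anterior/posterior dissections into dorsal/ventral classes
#'
#' Maps four dissection sample labels (\code{AD}, \code{PD}, \code{AV},
#' \code{PV}) to the two-region labels used for transfer.
#'
#' @param sample_labels Character vector of dissection labels.
#' @return Character vector over \code{"Dorsal"} / \code{"Ventral"}.
#' @export
combineDissections <- function(sample_labels) {
  map <- c(AD = "Dorsal", PD = "Dorsal", AV = "Ventral", PV = "Ventral")
  unknown <- setdiff(unique(sample_labels), names(map))
  if (length(unknown)) stop("unknown dissection label(s): ",
                            paste(unknown, collapse = ", "))
  unname(map[sample_labels])
}

#' Shared low-dimensional embedding of reference and query
#'
#' Default method is canonical correlation analysis: genes are intersected
#' and standardized within each dataset, and the singular value
#' decomposition of the reference x query cross-product yields paired
#' coordinates for both datasets, L2-normalized per cell. The alternative
#' projects the query onto the reference PCA. Component signs are fixed
#' (largest-magnitude coordinate positive) for determinism.
#'
#' @param ref_expr,query_expr Genes x cells normalized expression.
#' @param config A [transferConfig()].
#' @return List with \code{ref}, \code{query} (cells x n_dims coordinate
#'   matrices) and \code{d} (singular values or component variances).
#' @export
buildSharedEmbedding <- function(ref_expr, query_expr,
                                 config = transferConfig()) {
  genes <- intersect(rownames(ref_expr), rownames(query_expr))
  if (length(genes) < config$n_dims)
    stop("fewer shared genes (", length(genes), ") than n_dims")
  std <- function(m) {
    m <- m[genes, , drop = FALSE]
    s <- apply(m, 1, sd)
    s[s == 0] <- 1
    (m - rowMeans(m)) / s
  }
  x <- std(ref_expr); y <- std(query_expr)
  d_max <- min(ncol(x), ncol(y), length(genes))
  k <- min(config$n_dims, d_max)
  if (config$method == "cca") {
    sv <- svd(crossprod(x, y), nu = k, nv = k)
    dvals <- sv$d[seq_len(k)]
    ## scale coordinates by the singular values so dimensions carrying
    ## strong cross-dataset covariance dominate distances (the analogue of
    ## PCA scores being scaled by component standard deviations)
    ref_c <- sweep(sv$u, 2, dvals, "*")
    query_c <- sweep(sv$v, 2, dvals, "*")
  } else {
    pc <- prcomp(t(x), center = FALSE, rank. = k)
    ref_c <- pc$x
    query_c <- t(y) %*% pc$rotation
    dvals <- pc$sdev[seq_len(k)]^2
  }
  ## fixed sign: largest-magnitude coordinate (over both datasets) positive
  for (j in seq_len(k)) {
    v <- c(ref_c[, j], query_c[, j])
    if (v[which.max(abs(v))] < 0) {
      ref_c[, j] <- -ref_c[, j]; query_c[, j] <- -query_c[, j]
    }
  }
  l2 <- function(m) m / pmax(sqrt(rowSums(m^2)), 1e-12)
  rownames(ref_c) <- colnames(ref_expr)
  rownames(query_c) <- colnames(query_expr)
  list(ref = l2(ref_c), query = l2(query_c), d = dvals)
}

#' Find mutual-nearest-neighbor anchors in a shared embedding
#'
#' An anchor is a (reference, query) pair that are within each other's
#' \code{k_anchor} nearest cross-dataset neighbors. Each anchor is scored
#' by the Jaccard overlap of the pair's \code{k_filter}-neighborhoods in
#' the pooled embedding, min-max rescaled to [0, 1] within the anchor set;
#' anchors scoring below 0.1 after rescaling are dropped.
#'
#' @param emb Output of [buildSharedEmbedding()].
#' @param config A [transferConfig()].
#' @return An [AnchorSet-class].
#' @export
findAnchors <- function(emb, config = transferConfig()) {
  ref <- emb$ref; query <- emb$query
  k <- min(config$k_anchor, nrow(ref), nrow(query))
  nn_rq <- .knn_index(query, ref, k)   # per ref cell: its k NN among query
  nn_qr <- .knn_index(ref, query, k)   # per query cell: its k NN among ref
  pairs <- do.call(rbind, lapply(seq_len(nrow(ref)), function(i) {
    js <- nn_rq[i, ]
    js <- js[vapply(js, function(j) i %in% nn_qr[j, ], logical(1))]
    if (length(js)) cbind(ref = i, query = js) else NULL
  }))
  if (is.null(pairs) || nrow(pairs) == 0)
    stop("no mutual nearest neighbors found; raise k_anchor")

  pooled <- rbind(ref, query)
  kf <- min(config$k_filter, nrow(pooled) - 1L)
  nn_pool <- .knn_index(pooled, pooled, kf, drop_self = TRUE)
  jac <- vapply(seq_len(nrow(pairs)), function(a) {
    ni <- nn_pool[pairs[a, 1], ]
    nj <- nn_pool[nrow(ref) + pairs[a, 2], ]
    length(intersect(ni, nj)) / length(union(ni, nj))
  }, numeric(1))
  rng <- range(jac)
  score <- if (diff(rng) == 0) rep(1, length(jac)) else
    (jac - rng[1]) / diff(rng)
  keep <- score >= 0.1
  new("AnchorSet",
      ref = as.integer(pairs[keep, 1]), query = as.integer(pairs[keep, 2]),
      score = score[keep], ref_embedding = ref, query_embedding = query)
}

#' Transfer regional labels through anchors
#'
#' For every query cell, its \code{k_weight} nearest anchors (by distance
#' to the anchors' query-side cells in the shared embedding) are weighted
#' with a Gaussian kernel whose bandwidth is the distance to the
#' \code{k_weight}-th anchor, scaled by anchor score and normalized to sum
#' to one. The class score is the weighted sum of one-hot reference labels;
#' \code{net_score} is the Dorsal minus the Ventral score. Query cells
#' whose anchor weights all vanish receive uniform scores and are flagged.
#'
#' @param anchors An [AnchorSet-class].
#' @param ref_region_labels Region label per reference cell (the full
#'   reference the anchors index into).
#' @param config A [transferConfig()].
#' @return A [PredictedIdentity-class]; cells with vanishing weights are
#'   recorded in \code{attr(, "unanchored")}.
#' @export
transferLabels <- function(anchors, ref_region_labels,
                           config = transferConfig()) {
  if (!length(anchors@ref)) stop("anchor set is empty")
  labels <- as.character(ref_region_labels)
  classes <- sort(unique(labels))
  ## a regional transfer always reports both sides, even if the reference
  ## happens to carry only one, so the net score stays defined
  if (any(classes %in% c("Dorsal", "Ventral")))
    classes <- sort(unique(c(classes, "Dorsal", "Ventral")))
  if ("Dorsal" %in% classes)
    classes <- c("Dorsal", setdiff(classes, "Dorsal"))
  anchor_lab <- labels[anchors@ref]
  aq <- anchors@query_embedding[anchors@query, , drop = FALSE]
  n_query <- nrow(anchors@query_embedding)
  kw <- min(config$k_weight, length(anchors@ref))
  nn <- .knn_index(aq, anchors@query_embedding, kw)
  scores <- matrix(0, n_query, length(classes),
                   dimnames = list(rownames(anchors@query_embedding), classes))
  unanchored <- logical(n_query)
  for (q in seq_len(n_query)) {
    a_idx <- nn[q, ]
    d <- sqrt(colSums((t(aq[a_idx, , drop = FALSE]) -
                         anchors@query_embedding[q, ])^2))
    bw <- max(d[length(d)], 1e-8)
    w <- exp(-(d / bw)^2) * anchors@score[a_idx]
    if (sum(w) <= 0) {
      scores[q, ] <- 1 / length(classes)
      unanchored[q] <- TRUE
    } else {
      w <- w / sum(w)
      for (cl in classes)
        scores[q, cl] <- sum(w[anchor_lab[a_idx] == cl])
    }
  }
  net <- if (all(c("Dorsal", "Ventral") %in% classes))
    scores[, "Dorsal"] - scores[, "Ventral"] else rep(NA_real_, n_query)
  pred <- classes[apply(scores, 1, which.max)]  # ties: Dorsal first, then lexicographic
  out <- new("PredictedIdentity", scores = scores, net_score = net,
             predicted_class = pred)
  attr(out, "unanchored") <- which(unanchored)
  out
}

#' Tally predicted classes
#'
#' @param pred A [PredictedIdentity-class].
#' @return Named integer vector of argmax-class counts (ties were broken
#'   toward Dorsal, then lexicographically, in [transferLabels()]).
#' @export
predictedClassCounts <- function(pred) {
  cls <- colnames(pred@scores)
  vapply(cls, function(cl) sum(pred@predicted_class == cl), integer(1))
}
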