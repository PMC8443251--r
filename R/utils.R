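# Internal helpers shared across modules.

#' Truncated percentage formatting
#'
#' Formats \code{100 * k / n} truncated (not rounded) to one decimal place,
#' the convention used for QC and phase-fraction reporting (e.g. 4128 of
#' 35025 cells prints as "11.7\%").
#'
#' @param k Numerator count.
#' @param n Denominator count (> 0).
#' @param percent_sign Append a percent sign? Default \code{TRUE}.
#' @return Character scalar, one decimal, truncated.
#' @examples
#' percentTruncated(4128, 35025)  # "11.7%"
#' percentTruncated(691, 992)     # "69.6%"
#' @export
percentTruncated <- function(k, n, percent_sign = TRUE) {
  stopifnot(is.numeric(k), is.numeric(n), n > 0, k >= 0)
  ## truncate at one decimal; guard against floating error pushing e.g.
  ## 69.6 down to 69.5 (compute on integer-scaled value)
  val <- floor(100 * k / n * 10 + 1e-9) / 10
  out <- sprintf("%.1f", val)
  if (percent_sign) paste0(out, "%") else out
}

## quantile with linear interpolation between order statistics (type 7),
## the convention documented for every percentile rule in the package
.pctl <- function(x, p) {
  stats::quantile(x, probs = p / 100, type = 7, names = FALSE)
}

## Euclidean k-nearest neighbours of `query` rows among `ref` rows.
## Returns an n_query x k matrix of ref row indices, nearest first.
## drop_self removes the i-th ref row as a candidate for the i-th query row
## (only meaningful when ref and query are the same set of points).
## Brute force; intended for the problem sizes this package targets
## (thousands of cells, tens of dimensions).
.knn_index <- function(ref, query = ref, k, drop_self = FALSE) {
  ref <- as.matrix(ref); query <- as.matrix(query)
  stopifnot(ncol(ref) == ncol(query))
  if (drop_self) stopifnot(nrow(ref) == nrow(query))
  n_ref <- nrow(ref)
  k_eff <- min(k, n_ref - as.integer(drop_self))
  if (k_eff < 1L) stop("k_neighbors must leave at least one neighbour")
  ## squared distances via the expansion ||q - r||^2 = ||q||^2 - 2 q.r + ||r||^2
  d2 <- outer(rowSums(query^2), rep(1, n_ref)) -
    2 * query %*% t(ref) +
    outer(rep(1, nrow(query)), rowSums(ref^2))
  out <- matrix(NA_integer_, nrow(query), k_eff)
  for (i in seq_len(nrow(query))) {
    di <- d2[i, ]
    if (drop_self) di[i] <- Inf
    out[i, ] <- order(di)[seq_len(k_eff)]
  }
  out
}

## deterministic per-stage seed derivation from one pipeline seed
.derive_seed <- function(seed, stage) {
  offsets <- c(simulate = 101L, qc = 211L, preprocess = 307L, markers = 401L,
               transfer = 503L, scoring = 601L, grn = 701L, spatial = 809L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[stage]]
}
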