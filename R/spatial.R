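#' Normalize spot positions along a reference axis polyline
#'
#' Each spot's coordinate t in [0, 1] is the arclength of the nearest
#' point on the polyline (orthogonal projection onto each segment, clamped
#' to segment ends) divided by total arclength; 0 is the ventral-most
#' vertex, 1 the dorso-lateral wedge tip. Invariant to rigid transforms
#' applied jointly to spots and axis.
#'
#' @param spots \code{data.frame} with \code{x}, \code{y} columns
#'   (micrometers).
#' @param axis Two-column matrix of ordered polyline vertices.
#' @return \code{spots} with a \code{t} column added.
#' @export
normalizePositions <- function(spots, axis) {
  axis <- as.matrix(axis)
  if (nrow(axis) < 2) stop("axis polyline needs at least two vertices")
  seg <- diff(axis)
  len <- sqrt(rowSums(seg^2))
  if (sum(len) <= 0) stop("axis polyline has zero length")
  cum <- c(0, cumsum(len))
  total <- sum(len)
  pts <- cbind(spots$x, spots$y)
  t_out <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    best_d2 <- Inf; best_s <- 0
    for (k in seq_len(nrow(seg))) {
      v <- seg[k, ]
      w <- pts[i, ] - axis[k, ]
      f <- if (len[k] > 0) min(max(sum(w * v) / sum(v * v), 0), 1) else 0
      proj <- axis[k, ] + f * v
      d2 <- sum((pts[i, ] - proj)^2)
      if (d2 < best_d2) {
        best_d2 <- d2
        best_s <- cum[k] + f * len[k]
      }
    }
    t_out[i] <- best_s / total
  }
  spots$t <- t_out
  spots
}

#' Binned density profile and median of axis positions
#'
#' @param t Normalized axis coordinates in [0, 1].
#' @param n_bins Histogram bins over [0, 1] (default 50).
#' @return List with \code{breaks}, \code{density} (histogram density per
#'   bin) and \code{median} (sample median of t).
#' @export
densityProfile <- function(t, n_bins = 50) {
  if (!length(t)) stop("no spots supplied")
  h <- graphics::hist(t, breaks = seq(0, 1, length.out = n_bins + 1),
                      plot = FALSE)
  list(breaks = h$breaks, density = h$density, median = median(t))
}

#' Assign dorsal/ventral domain from axis position
#'
#' The dorsal domain is the most dorsal third of the axis (t >= 2/3,
#' boundary inclusive to dorsal); the ventral domain is the remaining two
#' thirds.
#'
#' @param t Normalized coordinates in [0, 1].
#' @param boundary Domain boundary (default 2/3).
#' @return Character vector over \code{"dorsal"} / \code{"ventral"}.
#' @export
domainAssign <- function(t, boundary = 2 / 3) {
  if (any(t < 0 | t > 1)) stop("t must lie in [0, 1]")
  ifelse(t >= boundary, "dorsal", "ventral")
}

#' Co-labeling percentage per domain
#'
#' Among spots/cells carrying the denominator flag, the percentage also
#' carrying the numerator flag, per domain, rounded to two decimals (e.g.
#' \code{97.67}). Domains with a zero denominator are omitted with a
#' warning.
#'
#' @param numerator,denominator Logical flags per spot.
#' @param domains Domain labels per spot.
#' @return Named numeric vector of percentages per domain.
#' @export
colabelFraction <- function(numerator, denominator, domains) {
  stopifnot(length(numerator) == length(denominator),
            length(numerator) == length(domains))
  out <- c()
  for (d in unique(domains)) {
    i <- domains == d
    den <- sum(denominator[i])
    if (den == 0) {
      warning("domain ", d, " has zero denominator; omitted")
      next
    }
    out[d] <- round(100 * sum(numerator[i] & denominator[i]) / den, 2)
  }
  out
}

#' Two-sample t test
#'
#' Equal-variance two-sample t test by default (Welch optional), matching
#' the pairwise comparisons used for spot quantifications. Degenerate
#' zero-variance input with equal means returns t = 0, p = 1.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @param var_equal Pool variances (default \code{TRUE}).
#' @return List with \code{t} and \code{p}.
#' @export
twoGroupTTest <- function(values_a, values_b, var_equal = TRUE) {
  stopifnot(length(values_a) >= 2, length(values_b) >= 2)
  if (sd(values_a) == 0 && sd(values_b) == 0) {
    if (mean(values_a) == mean(values_b)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(values_a) - mean(values_b)) * Inf, p = 0))
  }
  res <- t.test(values_a, values_b, var.equal = var_equal)
  list(t = unname(res$statistic), p = res$p.value)
}
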