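#' Quality-control thresholds
#'
#' Percentile-based cell filtering thresholds: cells are retained when
#' their UMI total lies inside the inclusive [P(umi_low), P(umi_high)]
#' band, their genes-per-cell is at or above P(genes_low), and their
#' mitochondrial fraction is at or below \code{mito_max_frac}. Percentiles
#' are computed on the input population with linear interpolation between
#' order statistics.
#'
#' @param umi_low_pct,umi_high_pct UMI-depth percentile band (defaults 5
#'   and 95).
#' @param genes_low_pct Lower genes-per-cell percentile (default 5).
#' @param mito_max_frac Maximum mitochondrial read fraction (default 0.10).
#' @return A named list of class \code{qc_thresholds}.
#' @export
qcThresholds <- function(umi_low_pct = 5, umi_high_pct = 95,
                         genes_low_pct = 5, mito_max_frac = 0.10) {
  stopifnot(umi_low_pct >= 0, umi_low_pct < umi_high_pct, umi_high_pct <= 100,
            genes_low_pct >= 0, genes_low_pct <= 100,
            mito_max_frac > 0, mito_max_frac <= 1)
  structure(list(umi_low_pct = umi_low_pct, umi_high_pct = umi_high_pct,
                 genes_low_pct = genes_low_pct, mito_max_frac = mito_max_frac),
            class = "qc_thresholds")
}

#' Filter cells on UMI depth, gene detection and mitochondrial content
#'
#' Removes cells outside the inclusive UMI percentile band, below the
#' genes-per-cell percentile, or above the mitochondrial fraction cap. A
#' cell failing several rules is attributed to the first failing rule in
#' the fixed order UMI, genes, mito, so the report is deterministic.
#' Because percentile bounds are population-relative, re-running the filter
#' on its own output can remove further cells; the filter is not
#' idempotent.
#'
#' @param counts Genes x cells non-negative integer matrix (or
#'   \code{SingleCellExperiment}).
#' @param thresholds A [qcThresholds()] list.
#' @param mito_gene_set Character vector of mitochondrial gene names. If
#'   empty, the mito rule is skipped with a warning.
#' @return List with \code{counts} (the retained columns, same class as
#'   input) and \code{report}, a [QcReport-class].
#' @examples
#' m <- matrix(rpois(600, 5), 20, 30,
#'             dimnames = list(paste0("g", 1:20), paste0("c", 1:30)))
#' res <- qcFilter(m, qcThresholds(), mito_gene_set = character(0))
#' @export
qcFilter <- function(counts, thresholds = qcThresholds(),
                     mito_gene_set = character(0)) {
  sce <- NULL
  if (methods::is(counts, "SummarizedExperiment")) {
    sce <- counts
    counts <- SummarizedExperiment::assay(counts, "counts")
  }
  if (ncol(counts) == 0L || nrow(counts) == 0L) stop("empty count matrix")
  bad_mito <- setdiff(mito_gene_set, rownames(counts))
  if (length(bad_mito)) stop("mito_gene_set outside the gene universe: ",
                             paste(head(bad_mito), collapse = ", "))

  umi <- Matrix::colSums(counts)
  n_detected <- Matrix::colSums(counts > 0)
  lo <- .pctl(umi, thresholds$umi_low_pct)
  hi <- .pctl(umi, thresholds$umi_high_pct)
  g_lo <- .pctl(n_detected, thresholds$genes_low_pct)

  fail_umi <- umi < lo | umi > hi
  fail_genes <- n_detected < g_lo
  if (length(mito_gene_set)) {
    mito_frac <- Matrix::colSums(counts[mito_gene_set, , drop = FALSE]) /
      pmax(umi, 1)
    fail_mito <- mito_frac > thresholds$mito_max_frac
  } else {
    warning("mito_gene_set is empty; mitochondrial rule skipped")
    fail_mito <- rep(FALSE, ncol(counts))
  }

  rule <- rep(NA_character_, ncol(counts))
  rule[fail_mito] <- "mito"
  rule[fail_genes] <- "genes"
  rule[fail_umi] <- "umi"   # last write wins: UMI takes attribution priority
  keep <- is.na(rule)

  report <- new("QcReport",
                n_input = ncol(counts),
                n_removed_by_rule = c(
                  umi = sum(rule == "umi", na.rm = TRUE),
                  genes = sum(rule == "genes", na.rm = TRUE),
                  mito = sum(rule == "mito", na.rm = TRUE)),
                n_retained = sum(keep),
                doublet_count = 0L)
  out_counts <- if (!is.null(sce)) sce[, keep] else counts[, keep, drop = FALSE]
  list(counts = out_counts, report = report)
}

#' Classify cells from sample-barcode counts
#'
#' Demultiplexes cells using per-barcode thresholds on log1p counts. For
#' each barcode, a kernel density estimate of its log1p count distribution
#' is scanned for modes; the threshold is the density minimum between the
#' two highest modes, falling back to the 75th percentile when the
#' distribution is unimodal. Cells above threshold for exactly one barcode
#' are singlets of that sample, above for two or more are doublets, and
#' above for none are negatives.
#'
#' @param bc Barcodes x cells non-negative count matrix.
#' @return \code{data.frame} with \code{call} (\code{"singlet"},
#'   \code{"doublet"}, \code{"negative"}) and \code{sample} (barcode name
#'   for singlets, \code{NA} otherwise), one row per cell.
#' @export
classifyBarcodes <- function(bc) {
  bc <- as.matrix(bc)
  if (any(bc < 0)) stop("barcode counts must be non-negative")
  lg <- log1p(bc)
  thr <- numeric(nrow(bc))
  for (b in seq_len(nrow(bc))) {
    x <- lg[b, ]
    if (all(bc[b, ] == 0)) {
      warning("barcode ", rownames(bc)[b] %||% b,
              " has all-zero counts; yields no calls")
      thr[b] <- Inf
      next
    }
    thr[b] <- .bimodal_threshold(x)
  }
  above <- lg > thr   # thresholds recycle per row
  n_above <- colSums(above)
  call <- ifelse(n_above == 0, "negative",
                 ifelse(n_above == 1, "singlet", "doublet"))
  bnames <- rownames(bc) %||% sprintf("BC%02d", seq_len(nrow(bc)))
  sample_id <- rep(NA_character_, ncol(bc))
  sing <- which(n_above == 1)
  if (length(sing))
    sample_id[sing] <- bnames[apply(above[, sing, drop = FALSE], 2, which)]
  data.frame(call = call, sample = sample_id,
             row.names = colnames(bc) %||% NULL,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## threshold splitting the two highest modes of a KDE; 75th percentile if
## effectively unimodal
.bimodal_threshold <- function(x) {
  if (length(unique(x)) < 3) return(.pctl(x, 75))
  d <- density(x, n = 512)
  y <- d$y
  is_max <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(is_max) < 2) return(.pctl(x, 75))
  top2 <- sort(is_max[order(y[is_max], decreasing = TRUE)][1:2])
  between <- seq(top2[1], top2[2])
  d$x[between[which.min(y[between])]]
}

#' Fold demultiplexing calls into a QC report
#'
#' @param report A [QcReport-class].
#' @param calls Output of [classifyBarcodes()].
#' @return The report with \code{doublet_count} set.
#' @export
addDoubletCounts <- function(report, calls) {
  report@doublet_count <- sum(calls$call == "doublet")
  validObject(report)
  report
}

#' Human-readable QC summary
#'
#' Percentages are truncated (not rounded) to one decimal place, so 4128
#' doublets among 35025 cells print as \code{"11.7\%"}.
#'
#' @param report A [QcReport-class].
#' @return Character vector of summary lines.
#' @examples
#' r <- new("QcReport", n_input = 35025L,
#'          n_removed_by_rule = c(umi = 0L, genes = 0L, mito = 0L),
#'          n_retained = 35025L, doublet_count = 4128L)
#' qcSummary(r)
#' @export
qcSummary <- function(report) {
  validObject(report)
  rem <- report@n_removed_by_rule
  c(sprintf("cells in: %d", report@n_input),
    sprintf("removed by UMI band: %d", rem[["umi"]]),
    sprintf("removed by gene detection: %d", rem[["genes"]]),
    sprintf("removed by mitochondrial fraction: %d", rem[["mito"]]),
    sprintf("retained: %d (%s)", report@n_retained,
            percentTruncated(report@n_retained, report@n_input)),
    sprintf("doublets: %d of %d (%s)", report@doublet_count, report@n_input,
            percentTruncated(report@doublet_count, report@n_input)))
}
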