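#' Write counts in CellRanger-style triplet layout
#'
#' Writes \code{matrix.mtx} (Matrix Market integer triplet),
#' \code{barcodes.tsv} (cell identifiers) and \code{features.tsv} (gene
#' identifiers) into \code{dir}.
#'
#' @param counts Genes x cells matrix (dense or \code{Matrix} sparse) or a
#'   \code{SingleCellExperiment} whose \code{counts} assay is used.
#' @param dir Output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
writeCountsMTX <- function(counts, dir) {
  if (methods::is(counts, "SummarizedExperiment"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  invisible(dir)
}

#' Read a CellRanger-style triplet layout
#'
#' @param dir Directory containing \code{matrix.mtx}, \code{barcodes.tsv},
#'   \code{features.tsv}.
#' @return Genes x cells sparse \code{dgCMatrix} with dimnames.
#' @export
readCountsMTX <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  rownames(m) <- readLines(file.path(dir, "features.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  m
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file: one set per line, tab-separated
#'   \code{name, description, gene1, gene2, ...}.
#' @return Named list of character vectors.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeGMT <- function(sets, path) {
  stopifnot(!is.null(names(sets)))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
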