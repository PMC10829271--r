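#' Validate a cells x tags count matrix
#'
#' Accepts a base matrix, a sparse `Matrix`, or a data frame and returns a
#' validated count matrix (cells as rows, tags as columns). Entries must be
#' non-negative integers; row (cell barcode) and column (tag) names must be
#' present and unique. Sparse inputs stay sparse.
#'
#' @param x Matrix-like object of UMI counts.
#' @return The validated matrix, cells x tags, with dimnames.
#' @export
as_tag_counts <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!(is.matrix(x) || methods::is(x, "Matrix")))
    stop("'x' must be a matrix of tag counts")
  v <- if (methods::is(x, "sparseMatrix")) x@x else as.vector(x)
  if (length(v) && (any(!is.finite(v)) || any(v < 0) ||
                    any(abs(v - round(v)) > 1e-8)))
    stop("tag counts must be non-negative integers")
  if (is.null(rownames(x)))
    rownames(x) <- paste0("cell", seq_len(nrow(x)))
  if (is.null(colnames(x)))
    colnames(x) <- paste0("tag", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x))) stop("duplicate cell barcodes")
  if (anyDuplicated(colnames(x))) stop("duplicate tag names")
  x
}

#' Per-cell total tag counts
#'
#' Row sums of the count matrix: each cell's total UMI count over all tags,
#' the single covariate of both GLM model spaces. Cells with total 0 carry no
#' information and are excluded from fitting downstream (and called
#' "negative").
#'
#' @param counts Cells x tags count matrix (see [as_tag_counts()]).
#' @return Named numeric vector of totals, one per cell.
#' @export
total_tag_counts <- function(counts) {
  counts <- as_tag_counts(counts)
  n <- Matrix::rowSums(counts)
  names(n) <- rownames(counts)
  n
}

#' Read a tag count matrix
#'
#' Reads CSV/TSV matrices (first column = cell barcodes, header = tag names)
#' or a MatrixMarket directory containing `matrix.mtx` with `barcodes.tsv`
#' and `features.tsv` sidecars. Orientation is auto-detected by default: the
#' longer axis is assumed to be cells, since multiplexed experiments have far
#' more cells than tags.
#'
#' @param path File (csv/tsv) or directory (mtx) to read.
#' @param format One of `"auto"`, `"csv"`, `"tsv"`, `"mtx"`.
#' @param cells_as `"auto"`, `"rows"` or `"cols"`: where cells live in the
#'   file on disk.
#' @return Cells x tags count matrix (sparse for mtx input).
#' @export
read_tag_matrix <- function(path, format = c("auto", "csv", "tsv", "mtx"),
                            cells_as = c("auto", "rows", "cols")) {
  format <- match.arg(format)
  cells_as <- match.arg(cells_as)
  if (format == "auto") {
    format <- if (dir.exists(path)) "mtx"
      else if (grepl("\\.csv$", path)) "csv"
      else "tsv"
  }
  if (format == "mtx") {
    mtx <- file.path(path, "matrix.mtx")
    bcf <- file.path(path, "barcodes.tsv")
    ftf <- file.path(path, "features.tsv")
    if (!file.exists(mtx) || !file.exists(bcf) || !file.exists(ftf))
      stop("mtx directory must contain matrix.mtx, barcodes.tsv, features.tsv")
    m <- Matrix::readMM(mtx)
    if (!methods::is(m, "dMatrix")) m <- m * 1   # pattern/logical -> numeric
    m <- methods::as(m, "CsparseMatrix")
    bc <- readLines(bcf)
    ft <- readLines(ftf)
    # conventional single-cell layout stores features x barcodes
    if (nrow(m) == length(ft) && ncol(m) == length(bc)) {
      dimnames(m) <- list(ft, bc)
      m <- Matrix::t(m)
    } else if (nrow(m) == length(bc) && ncol(m) == length(ft)) {
      dimnames(m) <- list(bc, ft)
    } else stop("sidecar lengths do not match matrix dimensions")
    return(as_tag_counts(m))
  }
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric entries in tag matrix")
  flip <- switch(cells_as,
                 rows = FALSE,
                 cols = TRUE,
                 auto = ncol(m) > nrow(m))
  if (flip) m <- t(m)
  as_tag_counts(m)
}

#' Write a tag count matrix
#'
#' Inverse of [read_tag_matrix()]; cells are written as rows for csv/tsv, and
#' in the conventional features x barcodes orientation for mtx directories.
#'
#' @param counts Cells x tags count matrix.
#' @param path Output file (csv/tsv) or directory (mtx).
#' @param format One of `"csv"`, `"tsv"`, `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_tag_matrix <- function(counts, path, format = c("csv", "tsv", "mtx")) {
  format <- match.arg(format)
  counts <- as_tag_counts(counts)
  if (format == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    m <- methods::as(methods::as(Matrix::t(
      Matrix::Matrix(as.matrix(counts), sparse = TRUE)), "generalMatrix"),
      "CsparseMatrix")
    Matrix::writeMM(m, file.path(path, "matrix.mtx"))
    writeLines(colnames(counts), file.path(path, "features.tsv"))
    writeLines(rownames(counts), file.path(path, "barcodes.tsv"))
    return(invisible(path))
  }
  sep <- if (format == "csv") "," else "\t"
  df <- data.frame(barcode = rownames(counts), as.matrix(counts),
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write classification results to a TSV table
#'
#' One row per cell, in input order: barcode, final call, then one posterior
#' column per tag. Output is plain-text and bitwise stable given identical
#' inputs.
#'
#' @param fit A `demux_fit` object from [demultiplex()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_demux_results <- function(fit, path) {
  stopifnot(inherits(fit, "demux_fit"))
  post <- fit$posterior
  df <- data.frame(barcode = rownames(post), call = fit$calls,
                   check.names = FALSE)
  colnames_post <- paste0("posterior.", colnames(post))
  pm <- as.matrix(post)
  colnames(pm) <- colnames_post
  df <- cbind(df, as.data.frame(pm, check.names = FALSE))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing"))
  on.exit(close(con))
  utils::write.table(format(df, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a classification results table written by [write_demux_results()]
#'
#' @param path TSV file path.
#' @return Data frame with `barcode`, `call` and posterior columns.
#' @export
read_demux_results <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = NA, stringsAsFactors = FALSE)
}
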