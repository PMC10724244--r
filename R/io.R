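# Readers/writers for dissimilarity matrices (dense and condensed), label
# files, and data matrices (dense CSV/TSV or sparse MatrixMarket), plus the
# dissimilarity metrics and adjacency construction.
#
# Condensed format: the N_d = n(n-1)/2 upper-triangle values in row-major
# i < j order, i.e. d(1,2), d(1,3), ..., d(1,n), d(2,3), ..., one value per
# line. This matches R's `lower.tri` column-major order for a symmetric
# matrix, and the storage order of a `dist` object.

#' Pairwise dissimilarities of a data matrix
#'
#' Computes one of five dissimilarity metrics between the rows of `x`:
#' Euclidean, maximum (Chebyshev), Manhattan, Canberra
#' (\eqn{\sum |x_i - y_i| / (|x_i| + |y_i|)}, zero-denominator terms
#' skipped), or binary (proportion of discordant nonzero indicators among
#' positions where at least one value is nonzero). Delegates to
#' [stats::dist], whose definitions match these conventions; a pair of
#' all-zero rows under binary/canberra has no informative position and is
#' assigned distance 0 with a warning.
#'
#' @param x numeric matrix, observations in rows.
#' @param metric one of `"euclidean"`, `"maximum"`, `"manhattan"`,
#'   `"canberra"`, `"binary"`.
#' @return a [stats::dist] object over the rows of `x`.
#' @export
compute_dissimilarity <- function(x, metric = c("euclidean", "maximum",
                                                "manhattan", "canberra",
                                                "binary")) {
  if (!is.matrix(x) || !is.numeric(x)) input_error("x must be a numeric matrix")
  if (ncol(x) < 1L) input_error("x needs at least one feature")
  if (anyNA(x)) {
    bad <- which(is.na(x), arr.ind = TRUE)[1L, ]
    input_error(sprintf("x contains missing values (first at row %d, column %d)",
                        bad[1L], bad[2L]))
  }
  metric <- match.arg(metric)
  if (metric %in% c("binary", "canberra")) {
    zero_rows <- which(rowSums(x != 0) == 0L)
    if (length(zero_rows) >= 2L)
      warning(sprintf(
        "%d all-zero observation pairs have no informative positions under '%s'; their distance is set to 0",
        choose(length(zero_rows), 2), metric))
  }
  if (metric == "canberra") return(stats::as.dist(canberra_matrix(x)))
  d <- stats::dist(x, method = metric)
  if (metric == "binary") d[is.na(d) | is.nan(d)] <- 0
  d
}

# plain Canberra sum: zero-denominator positions contribute nothing and are
# NOT rescaled (stats::dist renormalises dropped terms by f/n_used, which is
# a different convention)
canberra_matrix <- function(x) {
  n <- nrow(x)
  d <- matrix(0, n, n)
  ax <- abs(x)
  for (i in seq_len(n - 1L)) {
    rest <- (i + 1L):n
    num <- abs(x[rest, , drop = FALSE] -
                 matrix(x[i, ], length(rest), ncol(x), byrow = TRUE))
    den <- ax[rest, , drop = FALSE] +
      matrix(ax[i, ], length(rest), ncol(x), byrow = TRUE)
    frac <- num / den
    frac[den == 0] <- 0
    d[i, rest] <- rowSums(frac)
  }
  d + t(d)
}

#' Within-cluster adjacency mask over observation pairs
#'
#' Logical vector over the \eqn{n(n-1)/2} unique pairs, in condensed
#' (row-major i < j) order, `TRUE` where both observations share a label.
#' Its popcount is \eqn{|D_W|}.
#'
#' @param labels cluster assignment per observation.
#' @return logical vector of length `choose(n, 2)`.
#' @examples
#' adjacency_from_labels(c("A", "A", "B"))   # TRUE FALSE FALSE
#' @export
adjacency_from_labels <- function(labels) {
  labels <- as.integer(check_labels(labels, length(labels)))
  m <- outer(labels, labels, "==")
  m[lower.tri(m)]
}

infer_sep <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else ""

#' Read a dissimilarity matrix from a text file
#'
#' `format = "dense"` expects a square numeric grid (CSV or
#' whitespace/tab-separated by extension, optional header row);
#' `format = "condensed"` expects one value per line, the upper triangle in
#' row-major i < j order. `"auto"` picks condensed for single-column files.
#'
#' @param path file path.
#' @param format `"auto"`, `"dense"` or `"condensed"`.
#' @param header logical; dense input only.
#' @param sep field separator; inferred from the extension by default.
#' @return validated symmetric matrix (see [as_dissimilarity]).
#' @export
read_dissimilarity <- function(path, format = c("auto", "dense", "condensed"),
                               header = FALSE, sep = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) input_error(sprintf("file not found: %s", path))
  if (is.null(sep)) sep <- infer_sep(path)
  raw <- utils::read.table(path, header = header, sep = sep,
                           strip.white = TRUE)
  if (format == "auto") format <- if (ncol(raw) == 1L) "condensed" else "dense"
  if (format == "condensed") {
    if (ncol(raw) != 1L)
      input_error("condensed input must hold one value per line")
    vals <- raw[[1L]]
    if (!is.numeric(vals))
      input_error("condensed input contains non-numeric values")
    m <- condensed_to_matrix(vals)
  } else {
    m <- as.matrix(raw)
    if (!is.numeric(m)) {
      bad <- which(is.na(suppressWarnings(apply(raw, 2, as.numeric))),
                   arr.ind = TRUE)
      input_error(sprintf("non-numeric cell near line %d of %s",
                          if (length(bad)) bad[1L] + header else 1L, path))
    }
    dimnames(m) <- NULL
  }
  as_dissimilarity(m)
}

# inverse of matrix_to_condensed; length must be a triangular number
condensed_to_matrix <- function(vals) {
  l <- length(vals)
  n <- (1 + sqrt(1 + 8 * l)) / 2
  if (abs(n - round(n)) > 1e-9)
    input_error(sprintf(
      "condensed vector length %d is not n(n-1)/2 for any integer n", l))
  n <- round(n)
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- vals
  m + t(m)
}

matrix_to_condensed <- function(d) {
  d <- as_dissimilarity(d)
  d[lower.tri(d)]
}

#' Write a dissimilarity matrix
#'
#' @param d square symmetric matrix or `dist` object.
#' @param path output file; `.csv` writes comma-separated, else tabs.
#' @param format `"dense"` grid or `"condensed"` one-value-per-line upper
#'   triangle (row-major i < j order).
#' @export
write_dissimilarity <- function(d, path, format = c("dense", "condensed")) {
  format <- match.arg(format)
  d <- as_dissimilarity(d)
  if (format == "condensed") {
    writeLines(format(matrix_to_condensed(d), digits = 17, trim = TRUE,
                      scientific = FALSE), path)
  } else {
    utils::write.table(d, path, sep = if (infer_sep(path) == ",") "," else "\t",
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read cluster labels (one label per line)
#' @param path file path; labels are arbitrary strings, order matching the
#'   rows of the paired matrix. A single trailing blank line is ignored.
#' @return character vector.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) input_error(sprintf("file not found: %s", path))
  x <- readLines(path)
  while (length(x) > 0L && x[length(x)] == "") x <- x[-length(x)]
  if (length(x) == 0L) input_error(sprintf("label file is empty: %s", path))
  x
}

#' Write cluster labels, one per line
#' @param labels atomic vector.
#' @param path output file.
#' @export
write_labels <- function(labels, path) {
  writeLines(as.character(labels), path)
  invisible(path)
}

#' Read an observations x features data matrix
#'
#' Dense CSV/TSV (by extension), or sparse MatrixMarket (`.mtx`) densified
#' on read. Missing or non-numeric cells are an error, reported with their
#' position.
#'
#' @param path file path.
#' @param header logical, dense input only.
#' @return numeric matrix.
#' @export
read_data_matrix <- function(path, header = FALSE) {
  if (!file.exists(path)) input_error(sprintf("file not found: %s", path))
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    m <- as.matrix(Matrix::readMM(path))
    storage.mode(m) <- "double"
    return(m)
  }
  raw <- utils::read.table(path, header = header, sep = infer_sep(path),
                           strip.white = TRUE)
  m <- as.matrix(raw)
  # coercion NAs are reported below with their position instead
  suppressWarnings(storage.mode(m) <- "double")
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    input_error(sprintf(
      "missing or non-numeric value at line %d, column %d of %s",
      bad[1L] + header, bad[2L], path))
  }
  dimnames(m) <- NULL
  m
}

#' log2 transform with pseudocount 1
#'
#' The usual count-matrix normalisation `log2(x + 1)`; provided as an
#' explicit transform, never applied implicitly.
#' @param x numeric matrix of nonnegative values.
#' @return transformed matrix.
#' @export
normalize_log2 <- function(x) {
  if (any(x < 0)) input_error("log2 normalisation expects nonnegative values")
  log2(x + 1)
}

#' Keep the most variable features
#'
#' Plumbing filter: retains the `n_features` columns with the largest
#' sample variance.
#' @param x numeric matrix, features in columns.
#' @param n_features number of columns to keep.
#' @return submatrix of `x`.
#' @export
top_variance_features <- function(x, n_features) {
  if (n_features < 1 || n_features > ncol(x))
    input_error("n_features must be between 1 and ncol(x)")
  v <- apply(x, 2, stats::var)
  x[, order(-v)[seq_len(n_features)], drop = FALSE]
}
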