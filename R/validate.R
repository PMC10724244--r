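# Input validation and classed error conditions shared across the package.

input_error <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("hplus_input_error", "error", "condition"),
                      call = call))
}

degenerate_error <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("hplus_degenerate_error", "error", "condition"),
                      call = call))
}

degenerate_warning <- function(msg) {
  warning(warningCondition(msg, class = c("hplus_degenerate_warning",
                                          "warning", "condition")))
}

#' Validate and normalise a dissimilarity matrix
#'
#' Accepts a square numeric matrix or a [stats::dist] object and returns a
#' validated dense symmetric matrix with an exactly-zero diagonal. Matrices
#' that are asymmetric within a small relative tolerance are symmetrised by
#' averaging with their transpose; larger asymmetries are rejected, since a
#' proper dissimilarity is symmetric by definition.
#'
#' @param x square numeric matrix of pairwise dissimilarities, or a `dist`
#'   object.
#' @param tol relative tolerance for symmetry and for the diagonal;
#'   asymmetries up to `tol * max(1, max(|x|))` are averaged away.
#' @return a dense symmetric numeric matrix with zero diagonal.
#' @examples
#' d <- as_dissimilarity(dist(matrix(rnorm(20), 5)))
#' all(diag(d) == 0)
#' @export
as_dissimilarity <- function(x, tol = 1e-8) {
  if (inherits(x, "dist")) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    input_error("dissimilarity input must be a numeric matrix or a 'dist' object")
  n <- nrow(x)
  if (n != ncol(x)) input_error(sprintf(
    "dissimilarity matrix must be square (got %d x %d)", n, ncol(x)))
  if (n < 2L) input_error("need at least 2 observations (n >= 2)")
  if (!all(is.finite(x))) input_error("dissimilarity matrix contains non-finite values")
  scale <- max(1, max(abs(x)))
  asym <- max(abs(x - t(x)))
  if (asym > tol * scale)
    input_error(sprintf(
      "matrix is asymmetric beyond tolerance (max |d - t(d)| = %g)", asym))
  if (asym > 0) x <- (x + t(x)) / 2
  if (max(abs(diag(x))) > tol * scale)
    input_error("dissimilarity matrix diagonal must be zero")
  diag(x) <- 0
  x
}

# labels paired with an n-observation dissimilarity; returns a factor
check_labels <- function(labels, n) {
  if (is.null(labels) || length(labels) == 0L)
    input_error("labels must be a non-empty vector")
  if (length(labels) != n)
    input_error(sprintf("labels length (%d) does not match number of observations (%d)",
                        length(labels), n))
  if (anyNA(labels)) input_error("labels contain missing values")
  factor(labels)
}

# per-cluster proportions b_j from a label vector
group_balance <- function(labels) {
  tab <- table(labels)
  as.numeric(tab) / sum(tab)
}

check_balance <- function(balance, tol = 1e-8) {
  if (!is.numeric(balance) || length(balance) < 1L)
    input_error("balance must be a numeric vector")
  if (any(!is.finite(balance)) || any(balance <= 0))
    input_error("every balance entry must be finite and > 0")
  if (abs(sum(balance) - 1) > tol)
    input_error(sprintf("balance must sum to 1 (got %g)", sum(balance)))
  balance
}
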