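# Companion validity metrics for comparing candidate label sets: adjusted
# Rand index (external), mean silhouette and within-cluster sums of squares
# (internal). ARI and silhouette are implemented from their standard
# pair-counting / (b - a)/max(a, b) formulas so the package carries no hard
# dependency for them; tests cross-check against independent reference
# implementations.

#' Adjusted Rand index between two partitions
#'
#' Pair-counting agreement corrected for chance:
#' \deqn{ARI = \frac{\sum_{ij}\binom{n_{ij}}{2} - E}{\tfrac12(\sum_i\binom{a_i}{2} + \sum_j\binom{b_j}{2}) - E}}
#' with \eqn{E = \sum_i\binom{a_i}{2}\sum_j\binom{b_j}{2}/\binom{n}{2}}.
#' Identical partitions give 1; a chance-level partition gives about 0 (a
#' single-cluster prediction gives exactly 0 against any non-trivial truth).
#'
#' @param truth,predicted label vectors of equal length.
#' @return scalar in \eqn{[-1, 1]}.
#' @export
adjusted_rand_index <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    input_error("truth and predicted must have equal length")
  n <- length(truth)
  if (n < 2L) input_error("need at least 2 observations")
  tab <- table(truth, predicted)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Mean silhouette width
#'
#' For each observation, \eqn{a} is the mean dissimilarity to its own
#' cluster (excluding itself) and \eqn{b} the smallest mean dissimilarity
#' to any other cluster; its silhouette is \eqn{(b - a)/\max(a, b)}, with
#' singletons assigned 0. Returns the mean over observations.
#'
#' @inheritParams split_distances
#' @return scalar in \eqn{[-1, 1]}.
#' @export
mean_silhouette <- function(d, labels) {
  d <- as_dissimilarity(d)
  n <- nrow(d)
  labels <- check_labels(labels, n)
  k <- nlevels(labels)
  if (k < 2L) degenerate_error("silhouette needs at least two clusters")
  sizes <- tabulate(labels, k)
  # n x k matrix of summed dissimilarity to each cluster
  sums <- vapply(seq_len(k),
                 function(j) rowSums(d[, labels == levels(labels)[j],
                                       drop = FALSE]),
                 numeric(n))
  own <- as.integer(labels)
  sil <- numeric(n)
  for (i in seq_len(n)) {
    nj <- sizes[own[i]]
    if (nj == 1L) { sil[i] <- 0; next }
    a <- sums[i, own[i]] / (nj - 1)
    b <- min(sums[i, -own[i]] / sizes[-own[i]])
    sil[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(sil)
}

# WCSS from squared pairwise distances: for Euclidean d, the within-cluster
# sum of squares of cluster j equals sum_{i<i' in j} d^2 / n_j
wcss_from_dissimilarity <- function(d, labels) {
  d <- as_dissimilarity(d)
  labels <- check_labels(labels, nrow(d))
  total <- 0
  for (lev in levels(labels)) {
    idx <- which(labels == lev)
    if (length(idx) < 2L) next
    sub <- d[idx, idx]
    total <- total + sum(sub[lower.tri(sub)]^2) / length(idx)
  }
  total
}

#' Validity report over candidate label sets
#'
#' Computes, for each candidate labelling of the same dissimilarity matrix,
#' the exact H+ (and 1 - H+, so that larger is better), mean silhouette,
#' within-cluster sums of squares (exact for Euclidean distances), and --
#' when truth labels are supplied -- the adjusted Rand index. Degenerate
#' candidates (one cluster, or all singletons) are reported with `NA`
#' metrics rather than aborting the sweep. On well-separated synthetic data
#' with a known number of groups, `1 - h_plus` peaks at the true k.
#'
#' @param d square symmetric dissimilarity matrix or `dist` object.
#' @param label_sets list of candidate label vectors (named entries become
#'   row names).
#' @param truth optional reference labels for the ARI column.
#' @return data frame with one row per candidate: `k`, `h_plus`,
#'   `one_minus_h_plus`, `mean_silhouette`, `wcss`, and `ari` if truth is
#'   given.
#' @export
k_sweep_report <- function(d, label_sets, truth = NULL) {
  if (!is.list(label_sets) || length(label_sets) == 0L)
    input_error("label_sets must be a nonempty list of label vectors")
  d <- as_dissimilarity(d)
  rows <- lapply(label_sets, function(labels) {
    k <- length(unique(labels))
    hp <- tryCatch(
      suppressWarnings(discordance(d, labels)$h_plus),
      error = function(e) NA_real_)
    sil <- tryCatch(mean_silhouette(d, labels), error = function(e) NA_real_)
    out <- data.frame(
      k = k, h_plus = hp, one_minus_h_plus = 1 - hp,
      mean_silhouette = sil,
      wcss = wcss_from_dissimilarity(d, labels))
    if (!is.null(truth)) out$ari <- adjusted_rand_index(truth, labels)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(label_sets)
  out
}
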