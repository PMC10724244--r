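# Bootstrap estimation of H+ without the full n x n dissimilarity matrix.

#' Allocate a bootstrap sample across clusters
#'
#' Splits a per-bootstrap sample size `t` over the clusters in proportion to
#' the group balance, using largest-remainder rounding so the parts sum to
#' `t` exactly, with a floor of one observation per cluster so no cluster is
#' starved. Ties in the fractional remainders break toward the
#' earlier cluster.
#'
#' @param balance per-cluster proportions, positive, summing to 1.
#' @param t total sample size; must be at least the number of clusters.
#' @return integer vector `t_j` with `sum(t_j) == t` and all `t_j >= 1`.
#' @examples
#' allocate_strata(c(0.55, 0.30, 0.15), 10)   # 6 3 1
#' @export
allocate_strata <- function(balance, t) {
  balance <- check_balance(balance)
  k <- length(balance)
  if (length(t) != 1L || !is.finite(t) || t != round(t))
    input_error("t must be a single integer")
  if (t < k)
    input_error(sprintf(
      "t = %d is smaller than the number of clusters (%d); every cluster needs >= 1 sample",
      t, k))
  raw <- balance * t
  tj <- floor(raw)
  rem <- as.integer(round(t - sum(tj)))
  if (rem > 0L) {
    ord <- order(-(raw - tj), seq_len(k))
    tj[ord[seq_len(rem)]] <- tj[ord[seq_len(rem)]] + 1
  }
  # floor of 1: move samples from the largest strata to any empty ones
  while (any(tj == 0L)) {
    tj[which.max(tj)] <- max(tj) - 1
    tj[which(tj == 0L)[1L]] <- 1
  }
  as.integer(tj)
}

#' Bootstrap H+ estimate (stratified resampling)
#'
#' Estimates H+ by repeatedly drawing a small stratified sample of
#' observations (with replacement, `t_j` from cluster `j` in proportion to
#' the group balance), computing the exact H+ on the induced `t x t`
#' dissimilarity sub-problem, and averaging over `r` replicates. Because
#' each replicate touches only `t(t-1)/2` distances, the full `n x n`
#' matrix is never materialised when raw data are supplied.
#'
#' Sampling with replacement can duplicate an observation, contributing
#' zero within-distances to a replicate; this is the ordinary bootstrap
#' behaviour and is kept as-is. A replicate whose within or between set
#' comes out empty is redrawn (at most 10 times, then an error).
#'
#' @param x either an observations-by-features numeric matrix (dissimilarities
#'   are computed per replicate via `metric`) or a precomputed square
#'   dissimilarity matrix / [stats::dist] object (sub-indexed per replicate).
#' @param labels cluster assignment per observation; at least two clusters.
#' @param r number of bootstrap replicates; default `max(30, round(0.05 * n))`.
#' @param t per-replicate sample size (default 100).
#' @param seed optional RNG seed; fixed seed gives identical output.
#' @param metric dissimilarity used when `x` is a data matrix; one of
#'   `"euclidean"`, `"maximum"`, `"manhattan"`, `"canberra"`, `"binary"`.
#' @param is_dissimilarity force interpretation of a square `x`; by default
#'   a square symmetric matrix with zero diagonal is treated as a
#'   dissimilarity matrix.
#' @return object of class `"hpb_result"`: list with `h_b` (mean H+ over
#'   replicates), `estimates`, `sd`, and the configuration (`r`, `t`,
#'   `seed`, `metric`).
#' @examples
#' sim <- gaussian_mixture(n = 300, f = 20, b = 0.5, delta = 1, seed = 1)
#' hpb(sim$data, sim$labels, r = 20, t = 50, seed = 1)
#' @export
hpb <- function(x, labels, r = NULL, t = 100, seed = NULL,
                metric = "euclidean", is_dissimilarity = NULL) {
  if (inherits(x, "dist")) {
    x <- as.matrix(x)
    is_dissimilarity <- TRUE
  }
  if (!is.matrix(x) || !is.numeric(x))
    input_error("x must be a numeric matrix or a 'dist' object")
  if (is.null(is_dissimilarity))
    is_dissimilarity <- nrow(x) == ncol(x) &&
      max(abs(x - t(x))) <= 1e-8 * max(1, max(abs(x))) &&
      all(abs(diag(x)) <= 1e-12)
  if (is_dissimilarity) x <- as_dissimilarity(x)
  n <- nrow(x)
  labels <- check_labels(labels, n)
  k <- nlevels(labels)
  if (k < 2L)
    degenerate_error("bootstrap H+ needs at least two clusters")
  if (is.null(r)) r <- max(30, round(0.05 * n))
  if (r < 1) input_error("r must be >= 1")
  balance <- group_balance(labels)
  tj <- allocate_strata(balance, t)
  idx_by_cluster <- split(seq_len(n), labels)
  if (!is.null(seed)) set.seed(seed)
  estimates <- numeric(r)
  for (b in seq_len(r)) {
    for (attempt in 1:11) {
      if (attempt == 11L)
        degenerate_error(
          "bootstrap replicate produced an empty distance set 10 times in a row")
      idx <- unlist(lapply(seq_len(k), function(j)
        idx_by_cluster[[j]][sample.int(length(idx_by_cluster[[j]]), tj[j],
                                       replace = TRUE)]), use.names = FALSE)
      sub_labels <- labels[idx]
      d_sub <- if (is_dissimilarity) x[idx, idx, drop = FALSE]
               else as.matrix(compute_dissimilarity(x[idx, , drop = FALSE],
                                                    metric = metric))
      diag(d_sub) <- 0
      sp <- split_distances(d_sub, sub_labels)
      if (sp$n_within > 0L && sp$n_between > 0L) break
    }
    estimates[b] <- h_plus(count_s(sp$within, sp$between),
                           sp$n_within, sp$n_between)
  }
  structure(list(
    h_b = mean(estimates), estimates = estimates,
    sd = stats::sd(estimates),
    r = r, t = t, t_j = tj, seed = seed,
    metric = if (is_dissimilarity) NA_character_ else metric
  ), class = "hpb_result")
}

#' @export
print.hpb_result <- function(x, ...) {
  cat(sprintf("Bootstrap H+ estimate: h_b = %.6f  (sd = %.4f, r = %d, t = %d)\n",
              x$h_b, x$sd, x$r, x$t))
  invisible(x)
}
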