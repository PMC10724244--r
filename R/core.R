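# Exact discordance metrics: s, G+, H+, alpha, and expected values.
#
# All three statistics are functions of the multisets of within-cluster
# (D_W) and between-cluster (D_B) pairwise dissimilarities induced by a
# label vector on a dissimilarity matrix. s counts the ordered cross pairs
# (w, u), w in D_W, u in D_B, with w strictly greater than u; G+ scales s
# by the number of ways to compare any two of the N_d distances, while H+
# scales by |D_W||D_B| and is therefore an unbiased estimator of
# P(d_within > d_between), free of the group-balance bias that afflicts G+.

#' Split pairwise dissimilarities into within- and between-cluster sets
#'
#' Assigns each of the \eqn{N_d = n(n-1)/2} unique pairwise dissimilarities
#' to the within-cluster set \eqn{D_W} (both observations share a label) or
#' the between-cluster set \eqn{D_B}. The proportion of within-cluster
#' distances, \eqn{\alpha = |D_W| / N_d}, is determined entirely by the
#' group sizes (see [alpha_from_balance]).
#'
#' @param d square symmetric dissimilarity matrix, or a [stats::dist] object.
#' @param labels cluster assignment per observation; any atomic vector of
#'   length `n`.
#' @return an object of class `"distance_split"`: a list with elements
#'   `within`, `between` (numeric vectors), `n_within`, `n_between`,
#'   `n_distances`, `alpha`, `n`, `k`, and `counts` (observations per group).
#' @examples
#' d <- matrix(0, 3, 3)
#' d[lower.tri(d)] <- c(1, 5, 6); d <- d + t(d)
#' split_distances(d, c("A", "A", "B"))
#' @export
split_distances <- function(d, labels) {
  d <- as_dissimilarity(d)
  n <- nrow(d)
  labels <- check_labels(labels, n)
  # lower.tri in column-major order enumerates pairs (i<j) in row-major
  # i<j order of the upper triangle; same order as a condensed vector
  vals <- d[lower.tri(d)]
  adj <- adjacency_from_labels(labels)
  nd <- length(vals)
  within <- vals[adj]
  between <- vals[!adj]
  structure(list(
    within = within,
    between = between,
    n_within = length(within),
    n_between = length(between),
    n_distances = nd,
    alpha = length(within) / nd,
    n = n,
    k = nlevels(labels),
    counts = as.integer(table(labels))
  ), class = "distance_split")
}

#' Count concordance violations between two distance sets
#'
#' Computes \eqn{s}, the number of ordered cross pairs \eqn{(w, u)} with
#' \eqn{w \in D_W}, \eqn{u \in D_B} and \eqn{w > u} strictly; exactly-equal
#' pairs contribute zero. The count is obtained by sorting the between set
#' once and locating each within value by binary search
#' (\eqn{O(N_d \log N_d)}), which is exact -- no pairwise double loop is
#' ever formed.
#'
#' @param within numeric vector of within-cluster dissimilarities.
#' @param between numeric vector of between-cluster dissimilarities.
#' @return double scalar `s` (doubles, because `s` can exceed
#'   `.Machine$integer.max` for large inputs).
#' @examples
#' count_s(c(3, 1), 2)   # only 3 > 2
#' @export
count_s <- function(within, between) {
  if (length(within) == 0L || length(between) == 0L) return(0)
  if (anyNA(within) || anyNA(between))
    input_error("distance sets must not contain missing values")
  sb <- sort(between)
  # findInterval with left.open counts elements strictly smaller than each w
  sum(as.numeric(findInterval(within, sb, left.open = TRUE)))
}

# ties diagnostic: number of exactly-equal cross pairs
count_cross_ties <- function(within, between) {
  if (length(within) == 0L || length(between) == 0L) return(0)
  sb <- sort(between)
  leq <- findInterval(within, sb)                    # between <= w
  lt <- findInterval(within, sb, left.open = TRUE)   # between <  w
  sum(as.numeric(leq - lt))
}

#' G+ discordance index
#'
#' Scales the violation count `s` by \eqn{N_d(N_d - 1)/2}, the number of
#' ways to compare each unique distance to every other. G+ near zero means
#' high concordance (tight, separated clusters). Its expectation depends on
#' the proportion of within-cluster distances \eqn{\alpha}, and hence on the
#' group balance -- see [expected_g_plus] and [h_plus] for the unbiased
#' alternative.
#'
#' @param s violation count, as returned by [count_s].
#' @param n_distances total number of unique pairwise distances \eqn{N_d}.
#' @return G+ in \eqn{[0, 1]}.
#' @export
g_plus <- function(s, n_distances) {
  if (n_distances < 2) input_error("n_distances must be >= 2")
  n_distances <- as.numeric(n_distances)
  s / (n_distances * (n_distances - 1) / 2)
}

#' H+ discordance metric
#'
#' Scales the violation count `s` by \eqn{|D_W| |D_B|}, the number of
#' within-to-between comparisons actually made. H+ is the empirical
#' probability that a within-cluster dissimilarity strictly exceeds a
#' between-cluster one, and -- unlike [g_plus] -- its expectation does not
#' depend on the group balance. H+ is undefined for degenerate partitions
#' (a single cluster, or all-singleton clusters) because one of the two
#' distance sets is then empty.
#'
#' @param s violation count.
#' @param n_within,n_between sizes of the within- and between-cluster
#'   distance sets; both must be positive.
#' @return H+ in \eqn{[0, 1]}.
#' @export
h_plus <- function(s, n_within, n_between) {
  if (n_within <= 0)
    degenerate_error(paste0(
      "H+ is undefined: no within-cluster distances ",
      "(every cluster is a singleton, alpha = 0)"))
  if (n_between <= 0)
    degenerate_error(paste0(
      "H+ is undefined: no between-cluster distances ",
      "(single cluster, alpha = 1)"))
  s / (as.numeric(n_within) * as.numeric(n_between))
}

#' Exact discordance summary for a labelled dissimilarity matrix
#'
#' One call computing `s`, G+, H+, the within-distance proportion
#' \eqn{\alpha}, and a cross-set tie count (a diagnostic for heavily tied
#' inputs such as binary metrics, where the strict inequality in `s` makes
#' ties contribute zero). For a degenerate partition (k = 1 or
#' all-singletons) H+ is reported as `NA` with a warning while `s`, G+ and
#' \eqn{\alpha} are still returned.
#'
#' @inheritParams split_distances
#' @return an object of class `"hplus_discordance"`: a list with `s`,
#'   `g_plus`, `h_plus`, `alpha`, `n`, `k`, `n_within`, `n_between`,
#'   `n_distances`, `ties`.
#' @examples
#' sim <- gaussian_mixture(n = 60, f = 5, b = 0.5, delta = 2, seed = 1)
#' discordance(dist(sim$data), sim$labels)
#' @export
discordance <- function(d, labels) {
  sp <- split_distances(d, labels)
  s <- count_s(sp$within, sp$between)
  ties <- count_cross_ties(sp$within, sp$between)
  gp <- g_plus(s, sp$n_distances)
  hp <- if (sp$n_within > 0L && sp$n_between > 0L) {
    h_plus(s, sp$n_within, sp$n_between)
  } else {
    degenerate_warning(if (sp$n_within == 0L)
      "H+ undefined (all clusters are singletons); reporting NA" else
      "H+ undefined (single cluster); reporting NA")
    NA_real_
  }
  structure(list(
    s = s, g_plus = gp, h_plus = hp, alpha = sp$alpha,
    n = sp$n, k = sp$k,
    n_within = sp$n_within, n_between = sp$n_between,
    n_distances = sp$n_distances, ties = ties
  ), class = "hplus_discordance")
}

#' @export
print.hplus_discordance <- function(x, digits = 4, ...) {
  cat("Exact discordance (n =", x$n, ", k =", x$k, ")\n")
  cat(sprintf("  s        = %.0f\n", x$s))
  cat(sprintf("  G+       = %.*f\n", digits, x$g_plus))
  cat(sprintf("  H+       = %.*f\n", digits, x$h_plus))
  cat(sprintf("  alpha    = %.*f  (|D_W| = %d, |D_B| = %d)\n",
              digits, x$alpha, x$n_within, x$n_between))
  if (x$ties > 0)
    cat(sprintf("  ties     = %.0f exactly-equal cross pairs\n", x$ties))
  invisible(x)
}

#' Proportion of within-cluster distances from the group balance
#'
#' Closed form for \eqn{\alpha}, the fraction of the \eqn{N_d = n(n-1)/2}
#' pairwise distances that fall within a cluster, as a function of the
#' group balance \eqn{b}:
#' \deqn{\alpha = \frac{1}{n-1} \sum_j b_j (n b_j - 1).}
#' When `n * balance` are the integer group sizes this agrees exactly with
#' the empirical \eqn{\alpha} from [split_distances]. Fractional group
#' sizes are permitted and give the continuous extension of the formula.
#'
#' @param n number of observations.
#' @param balance per-group proportions \eqn{b_j}; positive, summing to 1.
#' @return \eqn{\alpha} as a scalar.
#' @examples
#' alpha_from_balance(1000, c(0.9, 0.1))   # 819/999, ~0.82
#' @export
alpha_from_balance <- function(n, balance) {
  if (length(n) != 1L || !is.finite(n) || n < 2)
    input_error("n must be a single number >= 2")
  balance <- check_balance(balance)
  sum(balance * (n * balance - 1)) / (n - 1)
}

#' Expected G+ under a given within-distance proportion
#'
#' Expectation of G+ conditional on \eqn{\alpha} and \eqn{N_d}:
#' \deqn{E[G_+] = \frac{N_d}{N_d - 1} \, 2\alpha(1-\alpha)\, P,}
#' where \eqn{P = P(d_{within} > d_{between})}. Under a null clustering
#' with equal distance distributions, \eqn{P = 1/2}, so E[G+] varies with
#' the balance purely through \eqn{2\alpha(1-\alpha)} -- the bias H+ removes.
#'
#' @param alpha proportion of within-cluster distances, in \eqn{[0, 1]}.
#' @param n_distances total number of pairwise distances \eqn{N_d}.
#' @param p_exceed probability a within distance exceeds a between distance;
#'   defaults to the null value 1/2.
#' @return expected G+.
#' @export
expected_g_plus <- function(alpha, n_distances, p_exceed = 0.5) {
  if (n_distances < 2) input_error("n_distances must be >= 2")
  if (alpha < 0 || alpha > 1) input_error("alpha must lie in [0, 1]")
  if (p_exceed < 0 || p_exceed > 1) input_error("p_exceed must lie in [0, 1]")
  (n_distances / (n_distances - 1)) * 2 * alpha * (1 - alpha) * p_exceed
}

#' Balance-penalized H+ (experimental)
#'
#' Divides H+ by `max(alpha, 1 - alpha)` to penalise degenerate labellings
#' that concentrate observations in one cluster (driving \eqn{\alpha} to 1),
#' or by `min(alpha, 1 - alpha)` to penalise the opposite degeneracy of many
#' tiny clusters (\eqn{\alpha} near 0). The `min` variant can exceed 1.
#' These penalties are exploratory heuristics, not part of the core metric.
#'
#' @param h H+ value in \eqn{[0, 1]}.
#' @param alpha within-distance proportion, strictly inside \eqn{(0, 1)}.
#' @param mode `"max"` or `"min"`.
#' @return penalised value.
#' @export
penalized_h_plus <- function(h, alpha, mode = c("max", "min")) {
  mode <- match.arg(mode)
  if (h < 0 || h > 1) input_error("h must lie in [0, 1]")
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    degenerate_error("alpha must lie strictly inside (0, 1) to penalize H+")
  h / switch(mode, max = max(alpha, 1 - alpha), min = min(alpha, 1 - alpha))
}
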