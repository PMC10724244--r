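# Independent oracles: deliberately naive double-loop implementations used
# to verify the sub-quadratic / sketch-based code paths, plus small
# instance generators.

# O(|W||B|) pairwise count of strict exceedances (and ties)
brute_count_s <- function(within, between) {
  s <- 0
  for (w in within) s <- s + sum(w > between)
  s
}

brute_h_plus <- function(within, between) {
  brute_count_s(within, between) /
    (as.numeric(length(within)) * length(between))
}

# exact H+ on raw sets via the package's (separately oracle-verified)
# rank counter; used as the reference for sketch-estimate error bounds
exact_h_plus <- function(within, between) {
  h_plus(count_s(within, between), length(within), length(between))
}

# literal double-loop Darboux-midpoint over sketch values, independent of
# the package's findInterval / boundary-walk paths
brute_sketch_h_e <- function(qw, qb) {
  p <- length(qw) - 1L
  s <- integer(p + 1L)
  for (i in seq_along(qw)) {
    for (j in seq_along(qb)) if (qb[j] < qw[i]) s[i] <- s[i] + 1L
  }
  lower <- 0; upper <- 0
  for (i in 1:p) lower <- lower + max(s[i] - 1L, 0L)        # columns 0..p-1
  for (i in 2:(p + 1L)) upper <- upper + min(s[i], p)       # columns 1..p
  (lower + upper) / (2 * p^2)
}

group_balance_of <- function(labels) {
  as.numeric(table(labels)) / length(labels)
}

# random small labelled dissimilarity instance (n <= n_max)
random_instance <- function(n_max = 25, k_max = 4) {
  n <- sample(3:n_max, 1)
  k <- sample(2:min(k_max, n - 1), 1)
  # guarantee at least one within pair and one between pair
  labels <- c(seq_len(k), sample(seq_len(k), n - k, replace = TRUE))[1:n]
  if (length(unique(labels)) < 2) labels[1] <- labels[1] %% k + 1
  x <- matrix(stats::rnorm(n * 3), n)
  list(d = as.matrix(stats::dist(x)), labels = labels, n = n, k = k)
}

# random pair of continuous distance sets with varied shape
random_distance_sets <- function(n_max = 4000, n_min = 30) {
  nw <- sample(n_min:n_max, 1)
  nb <- sample(n_min:n_max, 1)
  mu <- stats::runif(1, -2, 2)
  sg <- stats::runif(1, 0.2, 3)
  w <- stats::rnorm(nw, mu, sg)
  b <- stats::rnorm(nb, 0, 1)
  if (stats::runif(1) < 0.3) { w <- exp(w); b <- exp(b) }
  list(within = w, between = b)
}
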