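test_that("split_distances assigns every pair by label adjacency", {
  d <- matrix(0, 3, 3)
  d[lower.tri(d)] <- c(1, 5, 6)   # d12=1, d13=5, d23=6
  d <- d + t(d)
  sp <- split_distances(d, c("A", "A", "B"))
  expect_equal(sort(sp$within), 1)
  expect_equal(sort(sp$between), c(5, 6))
  expect_equal(sp$alpha, 1 / 3)
  expect_equal(sp$n_distances, 3)

  # single pair, same label: everything is within
  d2 <- matrix(c(0, 2, 2, 0), 2)
  sp2 <- split_distances(d2, c("A", "A"))
  expect_equal(sp2$n_within, 1)
  expect_equal(sp2$n_between, 0)
  expect_equal(sp2$alpha, 1)

  expect_error(split_distances(d, c("A", "B")), class = "hplus_input_error")
  expect_error(split_distances(matrix(0, 1, 1), "A"),
               class = "hplus_input_error")
})

test_that("empirical alpha for two groups of 500 matches the closed form", {
  labels <- rep(c("a", "b"), each = 500)
  d <- matrix(1, 1000, 1000); diag(d) <- 0
  sp <- split_distances(d, labels)
  expect_equal(sp$alpha, 499 / 999)
  expect_equal(sp$alpha, alpha_from_balance(1000, c(0.5, 0.5)))
})

test_that("count_s counts strict exceedances only", {
  expect_equal(count_s(c(3, 1), 2), 1)
  expect_equal(count_s(c(1, 2), c(3, 4)), 0)
  expect_equal(count_s(5, 5), 0)           # tie contributes nothing
  expect_equal(count_s(numeric(0), 1:3), 0)
})

test_that("count_s equals the double-loop oracle on random instances", {
  set.seed(101)
  for (rep in 1:200) {
    inst <- random_instance()
    sp <- split_distances(inst$d, inst$labels)
    expect_identical(count_s(sp$within, sp$between),
                     as.numeric(brute_count_s(sp$within, sp$between)))
  }
  # heavily tied integer-valued sets too
  set.seed(102)
  for (rep in 1:50) {
    w <- sample(0:5, sample(3:30, 1), replace = TRUE)
    b <- sample(0:5, sample(3:30, 1), replace = TRUE)
    expect_identical(count_s(w, b), as.numeric(brute_count_s(w, b)))
  }
})

test_that("G+ and H+ scale s by their respective denominators", {
  expect_equal(g_plus(1, 3), 1 / 3)
  expect_equal(g_plus(0, 10), 0)
  expect_error(g_plus(0, 1), class = "hplus_input_error")
  expect_equal(h_plus(1, 2, 1), 0.5)
  expect_error(h_plus(1, 0, 5), class = "hplus_degenerate_error")
  expect_error(h_plus(1, 5, 0), class = "hplus_degenerate_error")
})

test_that("discordance composes the pieces and reports ties", {
  d <- matrix(0, 3, 3)
  d[lower.tri(d)] <- c(1, 5, 6)
  d <- d + t(d)
  res <- discordance(d, c("A", "A", "B"))
  expect_equal(res$s, 0)
  expect_equal(res$g_plus, 0)
  expect_equal(res$h_plus, 0)
  expect_equal(res$alpha, 1 / 3)
  expect_equal(res$ties, 0)

  # relabeling leaves everything unchanged
  res2 <- discordance(d, c("B", "B", "A"))
  expect_equal(unclass(res2), unclass(res))

  # tie diagnostic: a within distance exactly equal to a between distance
  d3 <- matrix(0, 3, 3)
  d3[lower.tri(d3)] <- c(2, 2, 6)
  d3 <- d3 + t(d3)
  expect_equal(discordance(d3, c("A", "A", "B"))$ties, 1)
})

test_that("degenerate partitions yield NA H+ with a warning, G+ still reported", {
  d <- as.matrix(dist(matrix(rnorm(12), 4)))
  expect_warning(res <- discordance(d, rep("A", 4)),
                 class = "hplus_degenerate_warning")
  expect_true(is.na(res$h_plus))
  expect_equal(res$g_plus, 0)
  expect_equal(res$alpha, 1)
  expect_warning(res2 <- discordance(d, letters[1:4]),
                 class = "hplus_degenerate_warning")
  expect_true(is.na(res2$h_plus))
  expect_equal(res2$alpha, 0)
})

test_that("H+ identity, complementarity and bounds hold on random instances", {
  set.seed(7)
  for (rep in 1:50) {
    inst <- random_instance()
    sp <- split_distances(inst$d, inst$labels)
    if (sp$n_within == 0 || sp$n_between == 0) next
    res <- discordance(inst$d, inst$labels)
    nd <- sp$n_distances
    # h = g * Nd(Nd-1) / (2 |W||B|)
    expect_equal(res$h_plus,
                 res$g_plus * nd * (nd - 1) / (2 * sp$n_within * sp$n_between))
    expect_gte(res$h_plus, 0)
    expect_lte(res$h_plus, 1)
    # complementarity under no cross ties (continuous data)
    h_rev <- h_plus(count_s(sp$between, sp$within), sp$n_between, sp$n_within)
    expect_equal(res$h_plus + h_rev, 1)
    # empirical alpha agrees with the balance formula at integer counts
    expect_equal(sp$alpha, alpha_from_balance(sp$n, sp$counts / sp$n))
  }
})

test_that("H+ hits its endpoints exactly at full separation", {
  w <- c(1, 2, 3); b <- c(4, 5)
  expect_equal(h_plus(count_s(w, b), 3, 2), 0)     # max(W) <= min(B)
  expect_equal(h_plus(count_s(b + 10, w), 2, 3), 1) # min(W) > max(B)
})

test_that("alpha_from_balance matches its closed form", {
  expect_equal(alpha_from_balance(1000, c(0.9, 0.1)), 819 / 999)
  expect_equal(round(alpha_from_balance(1000, c(0.9, 0.1)), 2), 0.82)
  expect_equal(alpha_from_balance(50, 1.0), 1)
  expect_equal(alpha_from_balance(1000, c(0.5, 0.5)), 499 / 999)
  expect_error(alpha_from_balance(1, c(0.5, 0.5)), class = "hplus_input_error")
  expect_error(alpha_from_balance(10, c(0.5, 0.4)), class = "hplus_input_error")
})

test_that("expected G+ follows 2*alpha*(1-alpha)*P with finite-Nd correction", {
  nd <- 499500
  expect_equal(expected_g_plus(0.5, nd), (nd / (nd - 1)) * 0.25)
  expect_equal(expected_g_plus(0.82, nd, 0.5),
               (nd / (nd - 1)) * 2 * 0.82 * 0.18 * 0.5)
  expect_equal(round(expected_g_plus(819 / 999, nd, 0.5), 2), 0.15)
  expect_equal(expected_g_plus(0, nd), 0)
  expect_equal(expected_g_plus(1, nd), 0)
})

test_that("penalized H+ divides by the chosen balance extremum", {
  expect_equal(penalized_h_plus(0.5, 0.5, "max"), 1)
  expect_equal(penalized_h_plus(0.5, 0.5, "min"), 1)
  expect_equal(penalized_h_plus(0.5, 0.9, "max"), 0.5 / 0.9)
  expect_equal(penalized_h_plus(0.5, 0.9, "min"), 5)
  expect_error(penalized_h_plus(0.5, 1, "max"), class = "hplus_degenerate_error")
})

test_that("asymmetric or invalid matrices are rejected at ingestion", {
  m <- matrix(c(0, 1, 2, 0), 2)
  expect_error(as_dissimilarity(m), class = "hplus_input_error")
  # tiny asymmetry is averaged away
  m2 <- matrix(c(0, 1 + 1e-12, 1, 0), 2)
  expect_silent(d <- as_dissimilarity(m2))
  expect_identical(d, t(d))
  expect_error(as_dissimilarity(matrix(c(0, Inf, Inf, 0), 2)),
               class = "hplus_input_error")
  m3 <- diag(2); expect_error(as_dissimilarity(m3), class = "hplus_input_error")
})
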