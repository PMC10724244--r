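test_that("quantile sketch endpoints are exact min/max with interpolated interior", {
  s <- quantile_sketch(c(1, 2, 3, 4, 5), p = 4)
  expect_equal(s$values, c(1, 2, 3, 4, 5))
  expect_equal(s$p, 4)
  expect_equal(s$source_size, 5)

  expect_equal(quantile_sketch(7, p = 2)$values, c(7, 7, 7))

  set.seed(3)
  x <- rnorm(10000, 0.3)
  s2 <- quantile_sketch(x, p = 50)
  expect_equal(s2$values[1], min(x))
  expect_equal(s2$values[51], max(x))
  expect_equal(s2$values[26], median(x))
  expect_false(is.unsorted(s2$values))

  expect_error(quantile_sketch(numeric(0), 4), class = "hplus_input_error")
  expect_error(quantile_sketch(1:5, 1), class = "hplus_input_error")
})

test_that("both estimators short-circuit to exactly 0 or 1 on disjoint supports", {
  for (p in c(2, 5, 47)) {
    sw <- quantile_sketch(10:20, p)
    sb <- quantile_sketch(1:5, p)
    expect_equal(hpe_brute_force(sw, sb)$h_e, 1)
    expect_equal(hpe_grid_search(sw, sb)$h_e, 1)
    expect_equal(hpe_brute_force(sb, sw)$h_e, 0)
    expect_equal(hpe_grid_search(sb, sw)$h_e, 0)
  }
})

test_that("mismatched sketch resolutions are rejected", {
  expect_error(hpe_brute_force(quantile_sketch(1:9, 4), quantile_sketch(1:9, 5)),
               class = "hplus_input_error")
})

test_that("identical sketches of distinct values centre on one half", {
  for (p in c(4, 10, 33, 200)) {
    s <- quantile_sketch(seq_len(p + 1), p)   # p+1 distinct evenly spaced values
    bf <- hpe_brute_force(s, s)
    # Darboux midpoint closed form for the strictly-greater region of two
    # identical sketches; approaches the population value 1/2 as p grows
    expect_equal(bf$h_e, (p^2 - p + 1) / (2 * p^2))
    expect_equal(bf$h_e, brute_sketch_h_e(s$values, s$values))
    expect_equal(hpe_grid_search(s, s)$h_e, bf$h_e)
    expect_lt(abs(bf$h_e - 0.5), 1 / p)
  }
})

test_that("grid search agrees exactly with brute force, and both match the sketch oracle", {
  set.seed(11)
  for (rep in 1:100) {
    ds <- random_distance_sets(n_max = 500)
    p <- sample(c(2, 3, 5, 8, 16, 32), 1)
    sw <- quantile_sketch(ds$within, p)
    sb <- quantile_sketch(ds$between, p)
    bf <- hpe_brute_force(sw, sb)
    gs <- hpe_grid_search(sw, sb)
    expect_equal(gs$h_e, bf$h_e)
    expect_equal(bf$h_e, brute_sketch_h_e(sw$values, sb$values))
    expect_equal(sum(gs$z), gs$h_e)
  }
})

test_that("sketch estimates stay within 1/p of the exact H+", {
  # the guarantee belongs to the sketch-compression regime (p below the
  # sizes of the sets being sketched); at p comparable to the set size the
  # interpolation between order statistics adds error of order 1/size
  set.seed(13)
  n_checked <- 0
  for (rep in 1:200) {
    ds <- random_distance_sets(n_min = 2000, n_max = 8000)
    hp <- exact_h_plus(ds$within, ds$between)
    for (p in c(2, 4, 8, 16, 32, 64)) {
      sw <- quantile_sketch(ds$within, p)
      sb <- quantile_sketch(ds$between, p)
      expect_lt(abs(hpe_brute_force(sw, sb)$h_e - hp), 1 / p)
      expect_lt(abs(hpe_grid_search(sw, sb)$h_e - hp), 1 / p)
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 1200)
})

test_that("error shrinks along a doubling resolution ladder on a fixed instance", {
  set.seed(17)
  w <- rnorm(20000, 0.3)
  b <- rnorm(20000, -0.3)
  hp <- exact_h_plus(w, b)
  ladder <- c(8, 16, 32, 64, 128, 256, 512, 1024)
  errs <- vapply(ladder, function(p) {
    abs(hpe_grid_search(quantile_sketch(w, p), quantile_sketch(b, p))$h_e - hp)
  }, numeric(1))
  expect_true(all(errs < 1 / ladder))
  # finest resolution beats the coarsest (sampling noise aside)
  expect_lt(errs[length(errs)], errs[1] + 1e-12)
})

test_that("gamma candidates multiply back into the estimate's window", {
  set.seed(19)
  w <- rnorm(10000, 0.3)
  b <- rnorm(10000, -0.3)
  p <- 50
  res <- hpe_grid_search(quantile_sketch(w, p), quantile_sketch(b, p))
  g <- estimate_gammas(res)
  expect_gt(nrow(g), 0)
  expect_true(all(abs(g$gamma_w * g$gamma_b - res$h_e) <= 1 / (p - 1) + 1e-12))
  expect_true(all(diff(g$gamma_w) <= 0))   # reported with gamma_w descending

  # completely separated sets: the single pair (1, 1)
  sep <- hpe_grid_search(quantile_sketch(10:20, 10), quantile_sketch(1:5, 10))
  gsep <- estimate_gammas(sep)
  expect_equal(gsep, data.frame(gamma_w = 1, gamma_b = 1, product = 1))

  expect_error(estimate_gammas(hpe_brute_force(quantile_sketch(w, 10),
                                               quantile_sketch(b, 10))),
               class = "hplus_input_error")
})

test_that("the hpe() wrapper matches sketching the split distance sets", {
  set.seed(23)
  sim <- gaussian_mixture(n = 80, f = 10, b = 0.4, delta = 1, seed = 23)
  d <- as.matrix(dist(sim$data))
  sp <- split_distances(d, sim$labels)
  direct <- hpe_grid_search(quantile_sketch(sp$within, 32),
                            quantile_sketch(sp$between, 32))
  wrapped <- hpe(d, sim$labels, p = 32)
  expect_equal(wrapped$h_e, direct$h_e)
  expect_equal(wrapped$bound, 1 / 32)
  exact <- discordance(d, sim$labels)$h_plus
  expect_lt(abs(wrapped$h_e - exact), 1 / 32)
  withg <- hpe(d, sim$labels, p = 32, gammas = TRUE)
  expect_s3_class(withg$gamma_pairs, "data.frame")
  expect_error(hpe(d, rep("A", 80), p = 8), class = "hplus_degenerate_error")
})
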