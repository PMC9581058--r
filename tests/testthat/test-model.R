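test_that("grid construction enforces its invariants", {
  g <- tcspc_grid(0.016, 25)
  expect_equal(g$K, 1562L)              # floor(25 / 0.016)
  expect_equal(g$bin_start_times[1], 0)
  expect_true(all(diff(g$bin_start_times) > 0))
  expect_lte(g$K * g$delta_t, g$period)
  expect_error(tcspc_grid(0.05, 25, K = 3), "at least 4 bins")
  expect_error(tcspc_grid(-0.05, 25))
  expect_error(tcspc_grid(0.05, 25, K = 10000), "overruns")
})

test_that("decay parameter validation rejects invalid values", {
  expect_error(decay_params(-1, 0.2), "tau")
  expect_error(decay_params(2, 1.3), "b")
  expect_error(decay_params(2, 0.2, -5), "n_hat")
  p <- decay_params(2, 0.2, 100)
  expect_s3_class(p, "decay_params")
})

test_that("pure background gives uniform bin probabilities", {
  g <- small_grid()
  for (tau in c(0.3, 2, 7)) {
    p <- bin_probabilities(decay_params(tau, 1), g)
    expect_equal(p, rep(1 / g$K, g$K))
  }
})

test_that("integrated-mode probabilities sum to one across a parameter sweep", {
  for (dt in c(0.016, 0.05)) for (T in c(12.5, 25, 50)) {
    g <- tcspc_grid(dt, T)
    for (tau in c(0.1, 0.5, 2, 5)) for (b in c(0, 0.2, 0.9)) {
      p <- bin_probabilities(decay_params(tau, b), g, mode = "integrated")
      expect_equal(sum(p), 1, tolerance = 1e-12)
      expect_true(all(p >= 0))
    }
  }
})

test_that("point and integrated modes agree for narrow bins", {
  g <- full_grid()   # delta_t = 0.016 ns << tau
  p_int <- bin_probabilities(decay_params(2, 0.2), g, "integrated")
  p_pt <- bin_probabilities(decay_params(2, 0.2), g, "point")
  expect_lt(max(abs(p_int - p_pt)), 1e-5)
  # relative agreement whenever delta_t < tau / 50
  for (tau in c(1, 2, 4)) {
    g2 <- tcspc_grid(tau / 60, 25)
    a <- bin_probabilities(decay_params(tau, 0.1), g2, "integrated")
    b <- bin_probabilities(decay_params(tau, 0.1), g2, "point")
    expect_lt(max(abs(a - b) / a), 1e-4)
  }
})

test_that("probabilities approach the uniform limit as b -> 1", {
  g <- small_grid()
  for (b in c(0.9, 0.99, 0.999)) {
    p <- bin_probabilities(decay_params(2, b), g)
    expect_lt(max(abs(p - 1 / g$K)), (1 - b) * max(bin_probabilities(decay_params(2, 0), g)))
  }
})

test_that("expected counts scale probabilities by n_hat and decrease monotonically", {
  g <- small_grid()
  m <- expected_counts(decay_params(2, 1, 1000), g)
  expect_equal(m, rep(1000 / g$K, g$K))
  m2 <- expected_counts(decay_params(2, 0.2, 2000), g)
  expect_equal(sum(m2), 2000, tolerance = 1e-12)
  expect_true(all(diff(m2) < 0))     # exponential plus constant
  expect_error(expected_counts(decay_params(2, 0.2), g), "n_hat")
})

test_that("tail truncation drops the right bins and renormalizes", {
  g <- full_grid()
  x <- expected_counts(decay_params(2, 0.2, 1000), g)   # peak at bin 1
  # t_cut = 0 with peak at first bin: full vector
  tr0 <- truncate_tail(x, g, 0)
  expect_equal(tr0$values, x)
  # first ceil(0.2 / 0.016) = 13 bins from the peak onward removed
  tr <- truncate_tail(x, g, 0.2)
  expect_equal(length(tr$values), g$K - 13)
  expect_equal(tr$values[1], x[14])
  expect_equal(tr$grid$bin_start_times[1], 0)           # rebased
  # renormalized pattern sums to one
  trn <- truncate_tail(x, g, 0.2, renormalize = TRUE)
  expect_equal(sum(trn$values), 1)
  expect_error(truncate_tail(x, g, 30), "empty selection")
})

test_that("histogram rebinning sums adjacent bins and drops the remainder", {
  g <- tcspc_grid(0.1, 25, K = 103)
  h <- tcspc_histogram(rep(1, 103), g)
  h2 <- rebin_histogram(h, 10)
  expect_equal(h2$grid$K, 10L)
  expect_equal(h2$counts, rep(10, 10))
  expect_equal(h2$grid$delta_t, 1)
})

test_that("moment lifetime is exact for concentrated and clean exponential data", {
  g <- tcspc_grid(0.05, 25, K = 400)
  cnt <- numeric(400)
  cnt[21] <- 500                       # bin centered at 1.025 ns
  h <- tcspc_histogram(cnt, g)
  expect_equal(moment_lifetime(h), 20 * 0.05 + 0.025)  # center of bin 21
  # noise-free exponential, T = 100 tau, b = 0: within 1 % of tau
  g2 <- tcspc_grid(0.016, 200)
  h2 <- noise_free_histogram(decay_params(2, 0, 1e6), g2)
  expect_lt(abs(moment_lifetime(h2) - 2) / 2, 0.01)
  # background biases the estimate upward (toward T / 2 > tau)
  h3 <- noise_free_histogram(decay_params(2, 0.3, 1e6), g2)
  expect_gt(moment_lifetime(h3), moment_lifetime(h2))
})
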