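test_that("pattern libraries normalize columns and floor zeros", {
  set.seed(2)
  x <- matrix(rpois(40 * 3, 5), 40, 3)
  x[5, 2] <- 0
  lib <- pattern_library(x, labels = c("a", "b", "c"))
  expect_equal(colSums(lib$patterns), rep(1, 3), ignore_attr = TRUE)
  expect_true(all(is.finite(lib$log_patterns)))
  expect_error(pattern_library(cbind(x, 0)), "all zero")
  # model-grid library: S = n_tau * n_b columns
  g <- small_grid()
  lib2 <- decay_pattern_library(seq(0.5, 3, length.out = 20),
                                seq(0, 0.9, length.out = 6), g)
  expect_equal(lib2$S, 120L)
  expect_equal(colSums(lib2$patterns), rep(1, 120), ignore_attr = TRUE)
  expect_equal(nrow(lib2$labels), 120L)
})

test_that("the likelihood matrix equals the per-histogram score loop", {
  g <- small_grid()
  lib <- decay_pattern_library(seq(0.2, 4, length.out = 25),
                               c(0, 0.3, 0.7), g)
  set.seed(19)
  M <- flsmlm:::simulate_histogram_matrix(
    100, expected_counts(decay_params(1.7, 0.2, 300), g))
  lam <- neg_loglik_matrix(M, lib)
  for (j in sample(100, 20)) {
    for (s in sample(lib$S, 10)) {
      direct <- -sum(M[j, ] * lib$log_patterns[, s])
      expect_equal(lam[j, s], direct, tolerance = 1e-10)
    }
  }
  # all-zero histogram: zero row; doubling counts doubles the row
  expect_equal(neg_loglik_matrix(rep(0, g$K), lib)[1, ], rep(0, lib$S),
               ignore_attr = TRUE)
  expect_equal(neg_loglik_matrix(2 * M[1, ], lib), 2 * neg_loglik_matrix(M[1, ], lib))
  expect_error(neg_loglik_matrix(M[, 1:10], lib), "grid mismatch")
})

test_that("classification picks the generating pattern and breaks ties low", {
  g <- small_grid()
  lib <- decay_pattern_library(c(0.5, 1, 2, 4), c(0, 0.2, 0.5), g)
  # histogram proportional to a pattern is classified as that pattern
  for (s in c(2, 7, 11)) {
    m <- round(1e5 * lib$patterns[, s])
    expect_equal(classify_patterns(neg_loglik_matrix(m, lib)), s)
  }
  # duplicated column: deterministic tie to the first
  dup <- pattern_library(cbind(lib$patterns[, 3], lib$patterns[, 3]))
  lam <- neg_loglik_matrix(round(1e4 * lib$patterns[, 3]), dup)
  expect_equal(classify_patterns(lam), 1L)
  # single pattern: everything maps to it
  one <- pattern_library(lib$patterns[, 1])
  expect_equal(classify_patterns(neg_loglik_matrix(rbind(1:lib$K, 1), one)),
               c(1L, 1L))
})

test_that("posteriors are proper probabilities with the symmetries of a softmin", {
  g <- small_grid()
  lib <- decay_pattern_library(c(1, 2), c(0.1, 0.4), g)
  set.seed(29)
  M <- flsmlm:::simulate_histogram_matrix(
    30, expected_counts(decay_params(1.5, 0.2, 5000), g))
  lam <- neg_loglik_matrix(M, lib)
  f <- pattern_posterior(lam)
  expect_equal(rowSums(f), rep(1, 30))
  expect_true(all(f >= 0))
  # invariant under per-row shifts (likelihood offsets cancel)
  expect_equal(pattern_posterior(lam + 123.4), f, tolerance = 1e-12)
  # two identical patterns: posterior exactly 1/2 each, even at huge N
  dup <- pattern_library(cbind(lib$patterns[, 1], lib$patterns[, 1]))
  f2 <- pattern_posterior(neg_loglik_matrix(round(1e8 * lib$patterns[, 2]), dup))
  expect_equal(f2[1, ], c(0.5, 0.5), ignore_attr = TRUE)
})

test_that("grid fits return exact grid nodes and improve with finer grids", {
  g <- small_grid()
  tau_grid <- seq(0.5, 3, by = 0.25)
  b_grid <- seq(0, 0.8, by = 0.1)
  # noise-free histogram generated at a grid node comes back exactly
  m <- round(1e6 * flsmlm:::decay_pattern_matrix(1.75, 0.3, g))
  gf <- grid_fit(as.vector(m), g, tau_grid, b_grid)
  expect_equal(gf$tau_hat, 1.75)
  expect_equal(gf$b_hat, 0.3)
  # a superset grid can only lower the minimum score
  gf2 <- grid_fit(as.vector(m), g, sort(c(tau_grid, 1.9)), b_grid)
  expect_lte(gf2$lambda_min, gf$lambda_min)
})

test_that("rebinned grid search agrees with the full-resolution search", {
  g <- full_grid()
  set.seed(43)
  M <- flsmlm:::simulate_histogram_matrix(
    50, expected_counts(decay_params(2, 0.2, 1000), g))
  tau_grid <- seq(0.01, 3, length.out = 200)
  full <- grid_fit(M, g, tau_grid, seq(0, 0.9, length.out = 20), rebin = 1L)
  coarse <- grid_fit(M, g, tau_grid, seq(0, 0.9, length.out = 20), rebin = 8L)
  # coarsening is exact up to sub-bin information: estimates barely move
  expect_lt(median(abs(full$tau_hat - coarse$tau_hat)), 2 * diff(tau_grid[1:2]))
})

test_that("misclassification decreases with the number of photons", {
  g <- small_grid()
  pa <- bin_probabilities(decay_params(1.5, 0.2), g)
  pb <- bin_probabilities(decay_params(2.5, 0.2), g)
  lib <- pattern_library(cbind(pa, pb), labels = c("a", "b"))
  set.seed(47)
  err <- sapply(c(20, 100, 500), function(N) {
    Ma <- flsmlm:::simulate_histogram_matrix(300, N * pa)
    Mb <- flsmlm:::simulate_histogram_matrix(300, N * pb)
    pred <- classify_patterns(neg_loglik_matrix(rbind(Ma, Mb), lib))
    mean(pred != rep(c(1, 2), each = 300))
  })
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 0.05)
})

test_that("confidence filtering rejects ambiguous molecules", {
  g <- small_grid()
  pa <- bin_probabilities(decay_params(1.9, 0.2), g)
  pb <- bin_probabilities(decay_params(2.1, 0.2), g)
  lib <- pattern_library(cbind(pa, pb), labels = c("a", "b"))
  set.seed(53)
  M <- flsmlm:::simulate_histogram_matrix(200, 30 * pa)  # few photons: ambiguous
  res <- classify_histograms(M, lib, min_posterior = 0.9)
  expect_true(mean(res$accepted) < 0.5)
  expect_true(all(res$f_max >= 0.5 & res$f_max <= 1))
  expect_named(res, c("id", "best", "f_max", "accepted", "label", "f_1", "f_2"))
})
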