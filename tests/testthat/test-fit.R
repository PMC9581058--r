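test_that("every estimator recovers the truth from noise-free data", {
  g <- small_grid()
  truth <- decay_params(2, 0.2, 2e6)
  h <- noise_free_histogram(truth, g)
  for (k in c("neg_loglik", "pearson", "neyman1", "lsq", "poisson_deviance")) {
    f <- fit_decay(h, k, init = decay_params(1.4, 0.1, h$n))
    expect_lt(abs(f$tau_hat - 2), 1e-3)
    expect_lt(abs(f$b_hat - 0.2), 1e-3)
    expect_true(f$converged)
  }
})

test_that("the MLE implicitly fixes the expected photon number to N", {
  g <- small_grid()
  h <- simulate_histogram(decay_params(2, 0.2, 1500), g, seed = 4)
  f <- fit_decay(h, "neg_loglik")
  expect_equal(f$n_hat, h$n)
  expect_equal(sum(f$expected), h$n, tolerance = 1e-9)
})

test_that("minimizing the Poisson deviance reproduces the MLE estimates", {
  # with n_hat free, the deviance optimum coincides with the MLE in (tau, b)
  g <- small_grid()
  set.seed(9)
  for (i in 1:5) {
    h <- simulate_histogram(decay_params(2, 0.2, 800), g)
    f1 <- fit_decay(h, "neg_loglik", init = default_params(800))
    f2 <- fit_decay(h, "poisson_deviance", init = default_params(800))
    expect_equal(f2$tau_hat, f1$tau_hat, tolerance = 0.03)
    expect_equal(f2$b_hat, f1$b_hat, tolerance = 0.05)
  }
})

test_that("grid-search initial values make fits robust without a guess", {
  g <- small_grid()
  h <- simulate_histogram(decay_params(0.6, 0.3, 2000), g, seed = 13)
  f <- fit_decay(h, "neg_loglik")           # no init
  expect_equal(f$tau_hat, 0.6, tolerance = 0.1)
  expect_equal(f$b_hat, 0.3, tolerance = 0.1)
})

test_that("tail fits match full fits for an IRF-free mono-exponential decay", {
  g <- full_grid()
  h <- simulate_histogram(decay_params(2, 0.2, 5000), g, seed = 17)
  f_full <- fit_decay(h, "neg_loglik", init = default_params(5000))
  f_tail <- fit_decay(h, "neg_loglik", init = default_params(5000),
                      tail_cut = 0.2, peak_index = 1)
  expect_equal(f_tail$K_fit, g$K - 13)
  expect_equal(f_tail$tau_hat, f_full$tau_hat, tolerance = 0.05)
})

test_that("reconvolution fitting removes the IRF-induced lifetime bias", {
  g <- full_grid()
  irf <- test_irf()
  truth <- decay_params(0.4, 0.2, 20000)   # lifetime below the IRF width
  h <- simulate_histogram(truth, g, irf = irf, seed = 23)
  f_irf <- fit_decay(h, "neg_loglik", init = truth, irf = irf)
  expect_equal(f_irf$tau_hat, 0.4, tolerance = 0.05)
  f_plain <- fit_decay(h, "neg_loglik", tail_cut = 0.2)
  expect_gt(f_plain$tau_hat, f_irf$tau_hat)   # tail fit biased upward here
})

test_that("degenerate inputs raise informative fit errors", {
  g <- small_grid()
  expect_error(tcspc_histogram(rep(0, g$K), g) |> fit_decay("neg_loglik"),
               "no photons")
  expect_error(tcspc_histogram(rep(-1, g$K), g), "non-negative")
})

test_that("tidy and glance summarize decay fits", {
  g <- small_grid()
  h <- simulate_histogram(decay_params(2, 0.2, 2000), g, seed = 31)
  f <- fit_decay(h, "neg_loglik")
  td <- tidy(f)
  expect_equal(td$term, c("tau", "b", "n_hat"))
  expect_equal(td$estimate[1], f$tau_hat)
  expect_equal(td$std.error[1], f$sigma_tau)
  gl <- glance(f)
  expect_equal(gl$n_detected, h$n)
  expect_true(gl$converged)
})

test_that("batch fitting returns one molecule row per histogram", {
  g <- small_grid()
  mhat <- expected_counts(decay_params(2, 0.2, 500), g)
  set.seed(37)
  counts <- flsmlm:::simulate_histogram_matrix(25, mhat)
  tbl <- fit_decay_batch(counts, g)
  expect_equal(nrow(tbl), 25)
  expect_named(tbl, c("id", "n_photons", "tau_ns", "b", "n_hat", "red_chi2",
                      "sigma_tau_ns", "converged"))
  expect_equal(tbl$n_photons, rowSums(counts))
  expect_equal(median(tbl$tau_ns), 2, tolerance = 0.15)
})

test_that("IRF fitting recovers a known shifted Gamma from scattering data", {
  g <- full_grid()
  irf_true <- gamma_irf(t0 = 1.5, rho = 2.5, kappa = 4)
  q <- gamma_irf_curve(irf_true, g)$curve
  b_true <- 0.1
  mhat <- 1e6 * ((1 - b_true) * q + b_true / g$K)
  set.seed(41)
  h <- tcspc_histogram(rpois(g$K, mhat), g)
  f <- fit_irf(h)
  expect_equal(f$irf$rho, 2.5, tolerance = 0.02)
  expect_equal(f$irf$kappa, 4, tolerance = 0.02)
  expect_lt(abs(f$irf$t0 - 1.5), g$delta_t)
  # background recovered within Poisson error; empirical IRF normalized
  expect_equal(f$b, b_true, tolerance = 0.02)
  expect_equal(sum(f$empirical$curve), 1)
  # a peak in the second half of the window invalidates the bg estimate
  late <- c(rep(0, g$K - 50), rpois(50, 1e3 * q[1:50] + 1))
  expect_error(fit_irf(tcspc_histogram(late, g)), "background window")
})
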