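fake_records <- function(n, tau = 2, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    id = seq_len(n),
    psf_sigma_nm = runif(n, 90, 200),
    n_photons = round(exp(runif(n, log(10), log(5000)))),
    tau_ns = rnorm(n, tau, 0.1),
    b = runif(n, 0.1, 0.3),
    red_chi2 = rnorm(n, 1, 0.1)
  )
}

test_that("molecule filtering applies all three predicates with inclusive bounds", {
  rec <- tibble::tibble(
    id = 1:4,
    psf_sigma_nm = c(90, 150, 150, 150),
    n_photons = c(100, 25, 100, 100),
    tau_ns = 2, b = 0.2,
    red_chi2 = c(1, 1, 1.3, 1.0)
  )
  kept <- filter_molecules(rec)
  expect_equal(kept$id, c(2L, 4L))     # 90 nm too small, chi2 1.3 too large
  # boundary values are retained (25 photons, chi2 exactly 0.8/1.2)
  rec$red_chi2 <- c(0.8, 1.2, 0.79, 1.21)
  rec$psf_sigma_nm <- c(100, 180, 150, 150)
  rec$n_photons <- 25
  expect_equal(filter_molecules(rec)$id, c(1L, 2L))
})

test_that("photon grouping is contiguous, ordered and balanced", {
  rec <- fake_records(300)
  gr <- group_by_photons(rec, 30)
  expect_equal(as.vector(table(gr$photon_group)), rep(10, 30))
  means <- tapply(gr$n_photons, gr$photon_group, mean)
  expect_true(all(diff(means) > 0))
  # remainder goes to the highest-photon groups
  gr2 <- group_by_photons(fake_records(301), 30)
  sizes <- as.vector(table(gr2$photon_group))
  expect_equal(sort(unique(sizes)), c(10, 11))
  expect_equal(sizes[30], 11)
  expect_error(group_by_photons(fake_records(10), 30), "fewer molecules")
})

test_that("variance curves report unbiased group standard deviations and the CRLB", {
  rec <- group_by_photons(fake_records(600), 20)
  vc <- variance_curve(rec, period = 25)
  expect_equal(nrow(vc), 20)
  expect_true(all(diff(vc$mean_photons) > 0))
  g1 <- rec[rec$photon_group == 1, ]
  expect_equal(vc$sigma[1], sd(g1$tau_ns))     # n-1 denominator
  expect_equal(vc$crlb[1],
               crlb_sigma_tau(mean(g1$tau_ns), mean(g1$b),
                              mean(g1$n_photons), 25))
  expect_true(all(diff(vc$crlb) < 0))          # decays with photon number
})

test_that("intrinsic-variance fits recover the asymptote of a known curve", {
  # synthetic curve with known a, k, sigma_sample and tiny perturbations
  N <- exp(seq(log(30), log(5000), length.out = 30))
  sig <- 3 * N^-0.5 + 0.12
  curve <- tibble::tibble(photon_group = 1:30, mean_photons = N,
                          mean_tau = 2, mean_b = 0.2, sigma = sig,
                          group_size = 50,
                          crlb = crlb_sigma_tau(2, 0.2, N, 25))
  class(curve) <- c("variance_curve", class(curve))
  f <- fit_intrinsic_variance(curve)
  expect_equal(f$sigma_sample, 0.12, tolerance = 0.01)
  expect_equal(f$k, 0.5, tolerance = 0.05)
  # combined prediction dominates both components pointwise
  expect_true(all(f$curve$combined >= pmax(f$curve$crlb, f$sigma_sample) - 1e-12))
  expect_equal(tidy(f)$term, c("a", "k", "sigma_sample"))
  # the estimate only depends on lifetime spreads, not their location
  curve2 <- curve; curve2$mean_tau <- curve$mean_tau + 0.5
  f2 <- fit_intrinsic_variance(curve2)
  expect_equal(f2$sigma_sample, f$sigma_sample)
  expect_error(fit_intrinsic_variance(curve[1:3, ], min_mean_photons = 0),
               "at least 4")
})

test_that("ROC analysis matches an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(83)
  lab <- rep(c(0, 1), each = 150)
  sc <- rnorm(300, mean = lab * 0.8)
  ours <- classification_roc(sc, lab)
  ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours$auc, ref, tolerance = 1e-10)
})

test_that("ROC handles perfect, null and inverted scores", {
  lab <- rep(c(0, 1), each = 50)
  perfect <- classification_roc(c(rnorm(50, 0, 0.1), rnorm(50, 10, 0.1)), lab)
  expect_equal(perfect$auc, 1)
  set.seed(89)
  null <- classification_roc(rnorm(2000), rep(c(0, 1), 1000))
  expect_equal(null$auc, 0.5, tolerance = 0.05)
  # orientation auto-detected: inverted scores give the same AUC
  inv <- classification_roc(-c(rnorm(50, 0, 0.1), rnorm(50, 10, 0.1)), lab)
  expect_equal(inv$auc, 1)
  expect_true(inv$flipped)
  expect_error(classification_roc(rnorm(10), rep(1, 10)), "two classes")
})
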