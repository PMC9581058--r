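#' Simulate a TCSPC histogram
#'
#' Draws independent Poisson counts per bin with the model expectation
#' values as means (optionally after IRF reconvolution). The total photon
#' number is therefore itself Poisson-distributed around `n_hat`, not fixed.
#'
#' @param params A [decay_params()] with `n_hat` set.
#' @param grid A [tcspc_grid()].
#' @param irf Optional IRF; the expectation is circularly convolved with it.
#' @param mode See [bin_probabilities()].
#' @param seed Optional integer seed for bit-reproducible draws.
#' @return A [tcspc_histogram()].
#' @export
simulate_histogram <- function(params, grid, irf = NULL,
                               mode = "integrated", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mhat <- expected_counts(params, grid, mode)
  if (!is.null(irf)) mhat <- convolve_with_irf(mhat, irf_on_grid(irf, grid))
  tcspc_histogram(stats::rpois(grid$K, mhat), grid)
}

# J independent histograms with a common expectation, as a J x K matrix
simulate_histogram_matrix <- function(n, mhat) {
  K <- length(mhat)
  matrix(stats::rpois(n * K, rep(mhat, each = n)), nrow = n)
}

#' Simulate histograms from an explicit expectation vector
#'
#' Lower-level companion of [simulate_histogram()] for decay shapes outside
#' the mono-exponential model (e.g. multi-component mixtures assembled from
#' several expectation vectors).
#'
#' @param mhat Expected counts per bin.
#' @param grid The matching [tcspc_grid()].
#' @param n Number of independent histograms.
#' @param seed Optional seed.
#' @return A [tcspc_histogram()] if `n = 1`, otherwise an `n x K` matrix.
#' @export
simulate_from_expectation <- function(mhat, grid, n = 1, seed = NULL) {
  stopifnot(length(mhat) == grid$K, all(mhat >= 0))
  if (!is.null(seed)) set.seed(seed)
  if (n == 1) return(tcspc_histogram(stats::rpois(grid$K, mhat), grid))
  simulate_histogram_matrix(n, mhat)
}

#' Randomized low-precision initial values
#'
#' Multiplies each true parameter by an independent uniform draw from
#' `[0.5, 1.5]`, then clips into the valid domain. Emulates a deliberately
#' imprecise starting point for benchmarking fit robustness.
#'
#' @param true_params A [decay_params()].
#' @return A perturbed `decay_params`.
#' @export
randomized_init <- function(true_params) {
  u <- stats::runif(3, 0.5, 1.5)
  decay_params(
    tau = true_params$tau * u[1],
    b = min(true_params$b * u[2], 1),
    n_hat = if (is.na(true_params$n_hat)) NA_real_ else true_params$n_hat * u[3]
  )
}

#' Monte-Carlo comparison of lifetime estimators
#'
#' Simulates Poisson TCSPC histograms from the mono-exponential model and
#' fits each replicate with every requested score function, starting from
#' randomized initial values ([randomized_init()]). Summary statistics per
#' estimator and photon number are returned together with the CRLB at the
#' true parameters.
#'
#' @param photons Vector of expected photon numbers to simulate.
#' @param replicates Simulated histograms per cell.
#' @param kinds Score functions to compare (see [tcspc_score()]).
#' @param tau,b True lifetime (ns) and background fraction.
#' @param grid Simulation grid; defaults to `tcspc_grid(0.016, 25)`.
#' @param mode See [bin_probabilities()].
#' @param seed Integer seed; the harness is bit-reproducible under it.
#' @param keep_fits Also return the per-replicate estimates.
#' @return A tibble with one row per `(kind, n_photons)`: medians, means,
#'   standard deviations and 5/95% quantiles of the fitted `tau`, median of
#'   fitted `b` and `n_hat`, the CRLB `sigma_tau` at the truth, and the
#'   count of non-converged fits (excluded from the statistics). With
#'   `keep_fits = TRUE` the raw estimates are attached as attribute `fits`.
#' @export
estimator_benchmark <- function(photons = c(200, 2000), replicates = 1e4,
                                kinds = c("neg_loglik", "pearson", "neyman1"),
                                tau = 2, b = 0.2, grid = tcspc_grid(0.016, 25),
                                mode = "integrated", seed = 1,
                                keep_fits = FALSE) {
  stopifnot(replicates >= 2)
  kinds <- match.arg(kinds, score_kinds, several.ok = TRUE)
  set.seed(seed)
  cells <- tidyr::expand_grid(n_photons = photons, kind = kinds)
  raw <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    N <- cells$n_photons[ci]
    kind <- cells$kind[ci]
    truth <- decay_params(tau, b, N)
    mhat <- expected_counts(truth, grid, mode)
    counts <- simulate_histogram_matrix(replicates, mhat)
    est <- matrix(NA_real_, replicates, 3,
                  dimnames = list(NULL, c("tau", "b", "n")))
    conv <- logical(replicates)
    for (r in seq_len(replicates)) {
      h <- tcspc_histogram(counts[r, ], grid)
      f <- tryCatch(
        fit_decay(h, kind, init = randomized_init(truth), mode = mode,
                  compute_sigma = FALSE),
        error = function(e) NULL)
      if (!is.null(f)) {
        est[r, ] <- c(f$tau_hat, f$b_hat, f$n_hat)
        conv[r] <- f$converged
      }
    }
    ok <- conv & is.finite(est[, "tau"])
    raw[[ci]] <- tibble::tibble(
      kind = kind, n_photons = N,
      tau_true = tau, b_true = b,
      n_fits = sum(ok), n_failed = replicates - sum(ok),
      tau_median = stats::median(est[ok, "tau"]),
      tau_mean = mean(est[ok, "tau"]),
      tau_sd = stats::sd(est[ok, "tau"]),
      tau_q05 = stats::quantile(est[ok, "tau"], 0.05, names = FALSE),
      tau_q95 = stats::quantile(est[ok, "tau"], 0.95, names = FALSE),
      b_median = stats::median(est[ok, "b"]),
      n_hat_median = stats::median(est[ok, "n"]),
      crlb_sigma_tau = crlb_sigma_tau(tau, b, N, grid$period)
    )
    if (keep_fits) {
      raw[[ci]]$fits <- list(tibble::tibble(
        tau_hat = est[, "tau"], b_hat = est[, "b"], n_hat = est[, "n"],
        converged = conv))
    }
  }
  dplyr::bind_rows(raw)
}

#' Lifetime bias induced by the instrument response function
#'
#' Simulates decays reconvolved with a (typically measured or fitted) IRF
#' over a range of true lifetimes, then estimates each lifetime with a
#' grid-search MLE ([grid_fit()]) in three ways: a tail fit ignoring the
#' IRF, a full-curve fit reconvolved with the empirical IRF, and a
#' full-curve fit reconvolved with a parametric IRF. Reports the median
#' fitted lifetime and its bias per method and true lifetime.
#'
#' @param irf_sim IRF used to generate the data (empirical or parametric).
#' @param lifetimes True lifetimes in ns.
#' @param photons Expected photons per histogram.
#' @param replicates Histograms per lifetime.
#' @param methods Subset of `"tail"`, `"full_empirical"`, `"full_parametric"`.
#' @param irf_fit_empirical,irf_fit_parametric IRFs used by the two
#'   reconvolution methods; default to `irf_sim`.
#' @param b Background fraction of the simulated decays.
#' @param tau_grid,b_grid Search grids for the MLE grid fit.
#' @param tail_cut Tail cut-off in ns after the summed-decay maximum.
#' @param rebin Rebinning factor for the grid search (see [grid_fit()]).
#' @param grid Simulation grid; defaults to `tcspc_grid(0.016, 25)`.
#' @param seed Integer seed.
#' @return A tibble with one row per `(method, tau_true)`: `tau_median`,
#'   `bias` (median minus truth) and `n_fits`.
#' @export
irf_bias_benchmark <- function(irf_sim,
                               lifetimes = seq(0.025, 2, by = 0.025),
                               photons = 2000, replicates = 1000,
                               methods = c("tail", "full_empirical",
                                           "full_parametric"),
                               irf_fit_empirical = irf_sim,
                               irf_fit_parametric = irf_sim,
                               b = 0.2,
                               tau_grid = seq(0.01, 3, length.out = 500),
                               b_grid = seq(0, 0.9, length.out = 60),
                               tail_cut = 0.2, rebin = 8L,
                               grid = tcspc_grid(0.016, 25), seed = 1) {
  methods <- match.arg(methods, several.ok = TRUE)
  set.seed(seed)
  q_sim <- irf_on_grid(irf_sim, grid)
  nt <- length(tau_grid)
  # the reconvolution pattern libraries are lifetime-independent: build once
  logP <- list()
  for (me in setdiff(methods, "tail")) {
    irf_me <- if (me == "full_empirical") irf_fit_empirical else irf_fit_parametric
    P <- decay_pattern_matrix(tau_grid, b_grid, grid, irf = irf_me,
                              rebin = rebin)
    logP[[me]] <- log(pmax(P, 1e-12))
  }
  out <- vector("list", length(lifetimes) * length(methods))
  k <- 0
  for (tt in lifetimes) {
    mhat <- convolve_with_irf(
      expected_counts(decay_params(tt, b, photons), grid), q_sim)
    counts <- simulate_histogram_matrix(replicates, mhat)
    for (me in methods) {
      tau_fit <- if (me == "tail") {
        grid_fit(counts, grid, tau_grid, b_grid, tail_cut = tail_cut,
                 rebin = rebin)$tau_hat
      } else {
        M <- t(rebin_matrix_rows(t(counts), rebin))
        am <- grid_argmin(M, logP[[me]])
        tau_grid[(am$idx - 1L) %% nt + 1L]
      }
      k <- k + 1
      out[[k]] <- tibble::tibble(
        method = me, tau_true = tt,
        tau_median = stats::median(tau_fit),
        bias = stats::median(tau_fit) - tt,
        n_fits = length(tau_fit))
    }
  }
  dplyr::bind_rows(out)
}

#' Simulate a single-molecule sample with intrinsic lifetime variation
#'
#' Generates a set of localized molecules whose true lifetimes scatter
#' around `tau_mean` with standard deviation `sigma_sample` (normal,
#' truncated at positive lifetimes), emulating sample inhomogeneity beyond
#' photon (shot) noise. Per molecule, the expected photon number is drawn
#' from `photon_sampler` and a Poisson TCSPC histogram is simulated; the
#' PSF width is drawn uniformly from `psf_range` so that all records pass
#' the standard image-size filter.
#'
#' @param n_molecules Number of molecules.
#' @param tau_mean Mean lifetime in ns.
#' @param sigma_sample Intrinsic lifetime standard deviation in ns (>= 0).
#' @param b Background fraction.
#' @param photon_sampler Function `n -> n` expected photon counts; the
#'   default draws log-uniformly between 25 and 20000 photons, covering the
#'   photon range of typical dSTORM single-molecule data up to bright
#'   emitters. The bright end matters: the intrinsic-variance analysis can
#'   only anchor its asymptote if the brightest photon groups push the
#'   shot-noise contribution below the intrinsic spread.
#' @param psf_range PSF width range in nm.
#' @param grid Simulation grid; defaults to `tcspc_grid(0.016, 25)`.
#' @param mode See [bin_probabilities()].
#' @param seed Integer seed.
#' @return A list of class `sm_sample`: `records` (tibble with `id`, `x_nm`,
#'   `y_nm`, `psf_sigma_nm`, `n_photons`, `tau_true`, `b_true`), `counts`
#'   (the `n_molecules x K` histogram matrix) and `grid`.
#' @export
simulate_inhomogeneous_sample <- function(n_molecules, tau_mean = 2,
                                          sigma_sample = 0.1, b = 0.2,
                                          photon_sampler = function(n)
                                            round(exp(stats::runif(n, log(25), log(2e4)))),
                                          psf_range = c(100, 180),
                                          grid = tcspc_grid(0.016, 25),
                                          mode = "integrated", seed = 1) {
  stopifnot(sigma_sample >= 0, n_molecules >= 1)
  set.seed(seed)
  tau_i <- stats::rnorm(n_molecules, tau_mean, sigma_sample)
  while (any(tau_i <= 0.01)) {          # truncate at positive lifetimes
    bad <- tau_i <= 0.01
    tau_i[bad] <- stats::rnorm(sum(bad), tau_mean, sigma_sample)
  }
  n_i <- photon_sampler(n_molecules)
  counts <- matrix(0, n_molecules, grid$K)
  for (j in seq_len(n_molecules)) {
    mhat <- expected_counts(decay_params(tau_i[j], b, n_i[j]), grid, mode)
    counts[j, ] <- stats::rpois(grid$K, mhat)
  }
  records <- tibble::tibble(
    id = seq_len(n_molecules),
    x_nm = stats::runif(n_molecules, 0, 2e4),
    y_nm = stats::runif(n_molecules, 0, 2e4),
    psf_sigma_nm = stats::runif(n_molecules, psf_range[1], psf_range[2]),
    n_photons = rowSums(counts),
    tau_true = tau_i,
    b_true = b
  )
  structure(list(records = records, counts = counts, grid = grid),
            class = "sm_sample")
}

#' Simulate a two-species mixture for classification benchmarks
#'
#' Generates molecules of two species with different decay shapes. Each
#' species is described by (possibly multi-component) lifetimes and
#' amplitude weights, so that non-mono-exponential reference shapes can be
#' emulated. Returns the per-molecule histograms, true labels, and the two
#' noise-free reference patterns (the normalized expected decays of the
#' pure species).
#'
#' @param n_per_species Molecules per species.
#' @param species_a,species_b Lists with `tau` (vector of component
#'   lifetimes, ns), `weights` (amplitude fractions summing to 1) and `b`
#'   (background fraction).
#' @param photon_sampler Function `n -> n` expected photon counts.
#' @param grid Simulation grid.
#' @param seed Integer seed.
#' @return A list of class `species_mixture`: `counts` (`2n x K`), `labels`
#'   (factor `a` / `b`), `patterns` (`K x 2` reference matrix) and `grid`.
#' @export
simulate_species_mixture <- function(n_per_species = 1500,
                                     species_a = list(tau = c(1, 3),
                                                      weights = c(0.5, 0.5),
                                                      b = 0.2),
                                     species_b = list(tau = 2, weights = 1,
                                                      b = 0.2),
                                     photon_sampler = function(n)
                                       round(exp(stats::runif(n, log(50), log(2000)))),
                                     grid = tcspc_grid(0.016, 25), seed = 1) {
  set.seed(seed)
  shape <- function(sp) {
    stopifnot(abs(sum(sp$weights) - 1) < 1e-8)
    p <- numeric(grid$K)
    for (i in seq_along(sp$tau)) {
      p <- p + sp$weights[i] *
        bin_probabilities(decay_params(sp$tau[i], 0), grid)
    }
    (1 - sp$b) * p + sp$b / grid$K
  }
  pa <- shape(species_a); pb <- shape(species_b)
  n <- 2 * n_per_species
  nph <- photon_sampler(n)
  labels <- factor(rep(c("a", "b"), each = n_per_species), levels = c("a", "b"))
  counts <- matrix(0, n, grid$K)
  for (j in seq_len(n)) {
    p <- if (labels[j] == "a") pa else pb
    counts[j, ] <- stats::rpois(grid$K, nph[j] * p)
  }
  structure(list(counts = counts, labels = labels,
                 patterns = cbind(a = pa, b = pb), grid = grid),
            class = "species_mixture")
}
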