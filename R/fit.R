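default_fit_control <- function(control = list()) {
  utils::modifyList(list(reltol = 1e-6, maxit = 1e4), control)
}

# Model probabilities on the fitting window: full-grid model, optional IRF
# reconvolution, optional tail truncation with renormalization.
window_probabilities <- function(tau, b, grid, mode, irf_curve = NULL,
                                 idx = NULL) {
  p <- bin_probabilities(decay_params(tau, b), grid, mode)
  if (!is.null(irf_curve)) p <- convolve_with_irf(p, irf_curve)
  if (!is.null(idx)) {
    p <- p[idx]
    p <- p / sum(p)
  }
  p
}

#' Fit the mono-exponential decay model to a TCSPC histogram
#'
#' Estimates lifetime `tau`, background fraction `b` and (for all score
#' functions except the negative log-likelihood) the expected photon number
#' `n_hat` by Nelder-Mead simplex minimization of the chosen score. For
#' `kind = "neg_loglik"` the expected photon number is implicitly fixed to
#' the detected number of photons, so only `(tau, b)` are free.
#'
#' Internally the simplex works on unconstrained variables `log(tau)` and
#' `logit(b)` (and `log(n_hat)`), which enforces the parameter bounds
#' without constrained optimization. Non-convergence is flagged in the
#' result, not raised, so batch fits continue.
#'
#' @param hist A [tcspc_histogram()].
#' @param kind Score function, see [tcspc_score()].
#' @param init Optional [decay_params()] initial guess. When omitted, a
#'   coarse pattern-matching grid search supplies the starting point.
#' @param mode Probability discretization, see [bin_probabilities()].
#' @param tail_cut Optional tail-fit cut-off in ns after the peak
#'   (`peak_index`); bins before it are excluded and the model renormalized
#'   on the window.
#' @param peak_index Reference peak bin for the tail cut. Defaults to the
#'   histogram's own maximum; for single-molecule batches pass the peak of
#'   the summed decay.
#' @param irf Optional [empirical_irf()] or [gamma_irf()]; the model is
#'   circularly convolved with it before scoring (reconvolution fit).
#' @param control List with `reltol` and `maxit` for [stats::optim()].
#' @param compute_sigma Evaluate the CRLB at the fitted parameters
#'   (disable in tight Monte-Carlo loops where only the estimates matter).
#' @param restarts Number of simplex restarts from the previous optimum; a
#'   single restart guards against premature simplex collapse.
#' @return An object of class `decay_fit`: a list with `tau_hat`, `b_hat`,
#'   `n_hat`, `score_value`, `reduced_chi2` (Pearson, on the fitted window),
#'   `sigma_tau` (CRLB at the fitted parameters), `converged`, `n_detected`,
#'   `kind`, and the fitting window size `K_fit`.
#' @examples
#' g <- tcspc_grid(0.05, 25)
#' h <- simulate_histogram(decay_params(2, 0.2, 2000), g, seed = 1)
#' f <- fit_decay(h, "neg_loglik")
#' c(f$tau_hat, f$b_hat)
#' @export
fit_decay <- function(hist, kind = score_kinds, init = NULL,
                      mode = c("integrated", "point"), tail_cut = NULL,
                      peak_index = NULL, irf = NULL, control = list(),
                      compute_sigma = TRUE, restarts = 1L) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  stopifnot(inherits(hist, "tcspc_histogram"))
  if (hist$n < 1) stop("no photons in histogram", call. = FALSE)
  ctrl <- default_fit_control(control)
  grid <- hist$grid
  irf_curve <- if (!is.null(irf)) irf_on_grid(irf, grid) else NULL

  idx <- NULL
  m <- hist$counts
  if (!is.null(tail_cut)) {
    tr <- truncate_tail(hist$counts, grid, tail_cut,
                        peak_index = peak_index %||% which.max(hist$counts))
    idx <- tr$idx
    m <- tr$values
  }
  n_det <- sum(m)
  if (n_det < 1) stop("no photons in fitting window", call. = FALSE)
  K_fit <- length(m)

  if (is.null(init)) {
    gi <- grid_fit(matrix(hist$counts, nrow = 1), grid,
                   tau_grid = exp(seq(log(max(2 * grid$delta_t, 0.02)),
                                      log(grid$period / 3), length.out = 60)),
                   b_grid = seq(0, 0.9, length.out = 10),
                   mode = mode, irf = irf, tail_cut = tail_cut,
                   peak_index = peak_index)
    init <- decay_params(gi$tau_hat[1], min(gi$b_hat[1], 0.95), n_det)
  }
  free_n <- kind != "neg_loglik"

  clamp_b <- function(b) min(max(b, 1e-9), 1 - 1e-9)
  par0 <- c(log(init$tau), stats::qlogis(clamp_b(init$b)))
  if (free_n) par0 <- c(par0, log(if (is.na(init$n_hat)) n_det else init$n_hat))

  # hot loop: model and score inlined with data-dependent terms precomputed
  t_i <- grid$bin_start_times
  K <- grid$K
  dt <- grid$delta_t
  point_norm <- function(tau) tau * (-expm1(-grid$period / tau))
  pos <- which(m > 0)
  m_pos <- m[pos]
  log_m_pos <- log(m_pos)
  ney_den <- ifelse(m == 0, 1, m)
  # minimize the KL-shifted log-likelihood (same minimizer, but ~0 at the
  # optimum, so the simplex' relative tolerance maps to a tight parameter
  # tolerance instead of scaling with the raw score offset)
  kl_shift <- sum(m_pos * log_m_pos) - n_det * log(n_det)
  model_p <- function(tau, b) {
    if (mode == "integrated") {
      w <- exp(-t_i / tau) * (-expm1(-dt / tau))
      w <- w / sum(w)
      p <- (1 - b) * w + b / K
    } else {
      p <- dt * (1 - b) * exp(-(t_i + dt / 2) / tau) / point_norm(tau) + b / K
    }
    if (!is.null(irf_curve)) p <- convolve_with_irf(p, irf_curve)
    if (!is.null(idx)) {
      p <- p[idx]
      p <- p / sum(p)
    }
    p
  }
  objective <- function(par) {
    tau <- exp(par[1])
    if (!is.finite(tau) || tau <= 0) return(.Machine$double.xmax)
    b <- stats::plogis(par[2])
    p <- model_p(tau, b)
    s <- if (kind == "neg_loglik") {
      -sum(m_pos * log(p[pos])) + kl_shift
    } else {
      mh <- exp(par[3]) * p
      switch(kind,
        lsq = sum((mh - m)^2),
        pearson = sum((mh - m)^2 / mh),
        neyman1 = sum((mh - m)^2 / ney_den),
        poisson_deviance = 2 * (sum(m_pos * (log_m_pos - log(mh[pos]))) -
                                  n_det + sum(mh)))
    }
    if (!is.finite(s)) .Machine$double.xmax else s
  }

  opt <- stats::optim(par0, objective, method = "Nelder-Mead",
                      control = list(reltol = ctrl$reltol, maxit = ctrl$maxit))
  for (r in seq_len(restarts)) {
    opt <- stats::optim(opt$par, objective, method = "Nelder-Mead",
                        control = list(reltol = ctrl$reltol,
                                       maxit = ctrl$maxit))
  }
  tau_hat <- exp(opt$par[1])
  b_hat <- stats::plogis(opt$par[2])
  n_hat <- if (free_n) exp(opt$par[3]) else n_det
  p_hat <- window_probabilities(tau_hat, b_hat, grid, mode, irf_curve, idx)
  mhat <- n_hat * p_hat
  red2 <- if (K_fit > 3) sum((mhat - m)^2 / pmax(mhat, .Machine$double.xmin)) /
    (K_fit - 3) else NA_real_
  sigma_tau <- if (!compute_sigma) NA_real_ else tryCatch(
    crlb_sigma_tau(tau_hat, min(b_hat, 1 - 1e-9), max(n_det, 1), grid$period),
    error = function(e) NA_real_)

  score_value <- if (kind == "neg_loglik") opt$value - kl_shift else opt$value
  structure(list(
    tau_hat = tau_hat, b_hat = b_hat, n_hat = n_hat,
    score_value = score_value, reduced_chi2 = red2, sigma_tau = sigma_tau,
    converged = opt$convergence == 0, n_detected = n_det,
    kind = kind, K_fit = K_fit, expected = mhat, counts = m,
    period = grid$period
  ), class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "<decay_fit:%s> tau = %.4g ns (CRLB sigma %.3g), b = %.3g, N = %.4g photons, chi2/nu = %.3g%s\n",
    x$kind, x$tau_hat, x$sigma_tau, x$b_hat, x$n_detected, x$reduced_chi2,
    if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_decay
#' @param x A `decay_fit` object.
#' @param ... Unused.
#' @method tidy decay_fit
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(
    term = c("tau", "b", "n_hat"),
    estimate = c(x$tau_hat, x$b_hat, x$n_hat),
    std.error = c(x$sigma_tau, NA_real_, NA_real_)
  )
}

#' @rdname fit_decay
#' @method glance decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(
    kind = x$kind, score = x$score_value, reduced_chi2 = x$reduced_chi2,
    sigma_tau = x$sigma_tau, n_detected = x$n_detected,
    n_bins = x$K_fit, converged = x$converged
  )
}

#' Batch-fit single-molecule TCSPC histograms
#'
#' Fits every row of a histogram matrix with [fit_decay()], using one shared
#' pattern-matching grid search for the initial values and (for tail fits)
#' the peak of the summed decay as the common cut-off reference.
#'
#' @param counts `J x K` matrix of per-molecule counts.
#' @param grid The common [tcspc_grid()].
#' @param kind,mode,tail_cut,irf,control Passed to [fit_decay()].
#' @param init_tau_grid,init_b_grid Grids for the shared initial-guess
#'   pattern search.
#' @return A tibble with one row per molecule: `id`, `n_photons`, `tau_ns`,
#'   `b`, `n_hat`, `red_chi2`, `sigma_tau_ns`, `converged`.
#' @export
fit_decay_batch <- function(counts, grid, kind = "neg_loglik",
                            mode = "integrated", tail_cut = NULL, irf = NULL,
                            init_tau_grid = NULL, init_b_grid = seq(0, 0.9, length.out = 12),
                            control = list()) {
  stopifnot(is.matrix(counts), ncol(counts) == grid$K)
  J <- nrow(counts)
  peak <- which.max(colSums(counts))
  if (is.null(init_tau_grid))
    init_tau_grid <- exp(seq(log(max(2 * grid$delta_t, 0.02)),
                             log(grid$period / 3), length.out = 100))
  ini <- grid_fit(counts, grid, init_tau_grid, init_b_grid, mode = mode,
                  irf = irf, tail_cut = tail_cut, peak_index = peak,
                  rebin = max(1L, floor(0.1 / grid$delta_t)))
  res <- vector("list", J)
  for (j in seq_len(J)) {
    h <- tcspc_histogram(counts[j, ], grid)
    f <- tryCatch(
      fit_decay(h, kind,
                init = decay_params(ini$tau_hat[j], min(ini$b_hat[j], 0.95),
                                    max(h$n, 1)),
                mode = mode, tail_cut = tail_cut, peak_index = peak,
                irf = irf, control = control),
      error = function(e) NULL)
    res[[j]] <- if (is.null(f)) {
      tibble::tibble(id = j, n_photons = sum(counts[j, ]), tau_ns = NA_real_,
                     b = NA_real_, n_hat = NA_real_, red_chi2 = NA_real_,
                     sigma_tau_ns = NA_real_, converged = FALSE)
    } else {
      tibble::tibble(id = j, n_photons = f$n_detected, tau_ns = f$tau_hat,
                     b = f$b_hat, n_hat = f$n_hat, red_chi2 = f$reduced_chi2,
                     sigma_tau_ns = f$sigma_tau, converged = f$converged)
    }
  }
  dplyr::bind_rows(res)
}

#' Fit an instrument response function to a scattering measurement
#'
#' Given the TCSPC histogram of a fast scatterer (e.g. gold-film
#' back-scattering), this determines both a normalized empirical IRF and a
#' parametric shifted-Gamma IRF.
#'
#' The background level is estimated as the average count in the second half
#' of the histogram. The empirical IRF is the background-subtracted
#' histogram (negative bins clipped to zero) divided by its sum. The
#' parametric model `(1 - b) q_i + b / K`, with `q_i` the shifted-Gamma
#' curve, is fitted by minimizing the negative log-likelihood over
#' `(t0, rho, kappa, b)` with a Nelder-Mead simplex.
#'
#' @param hist A [tcspc_histogram()] of the scattering measurement, with a
#'   dominant unimodal peak in the first half of the window.
#' @param control List with `reltol` and `maxit`.
#' @return A list of class `irf_fit`: `irf` (the fitted [gamma_irf()]),
#'   `b` (fitted background fraction), `empirical` (the normalized
#'   [empirical_irf()]), `background_level` (counts per bin), `score_value`
#'   and `converged`.
#' @export
fit_irf <- function(hist, control = list()) {
  stopifnot(inherits(hist, "tcspc_histogram"))
  ctrl <- default_fit_control(control)
  m <- hist$counts
  grid <- hist$grid
  K <- grid$K
  pk <- which.max(m)
  if (pk > K / 2)
    stop("background window: the IRF peak lies in the second half of the histogram",
         call. = FALSE)
  bg <- mean(m[(floor(K / 2) + 1):K])
  emp <- pmax(m - bg, 0)
  if (sum(emp) <= 0) stop("invalid IRF: nothing above background", call. = FALSE)
  empirical <- empirical_irf(emp, grid)

  # Moment-based initial values for the shifted Gamma
  tc <- bin_centers(grid)
  w <- emp / sum(emp)
  above <- which(emp > 0.05 * max(emp))
  t0_0 <- max(grid$bin_start_times[above[1]] - 2 * grid$delta_t, 0)
  mu1 <- sum(w * (tc - t0_0))
  v1 <- max(sum(w * (tc - t0_0 - mu1)^2), (grid$delta_t)^2)
  rho_0 <- max(mu1^2 / v1, 1.05)
  kap_0 <- max(mu1 / v1, 1e-3)
  b_0 <- min(max(bg * K / sum(m), 1e-6), 0.9)

  objective <- function(par) {
    t0 <- par[1]
    if (t0 < 0 || t0 >= grid$period) return(.Machine$double.xmax)
    rho <- exp(par[2]); kap <- exp(par[3]); b <- stats::plogis(par[4])
    q <- tryCatch(gamma_irf_curve(gamma_irf(t0, rho, kap), grid)$curve,
                  error = function(e) NULL)
    if (is.null(q)) return(.Machine$double.xmax)
    s <- tcspc_score("neg_loglik", m, probs = (1 - b) * q + b / K)
    if (!is.finite(s)) .Machine$double.xmax else s
  }
  par0 <- c(t0_0, log(rho_0), log(kap_0), stats::qlogis(b_0))
  opt <- stats::optim(par0, objective, method = "Nelder-Mead",
                      control = list(reltol = ctrl$reltol, maxit = ctrl$maxit))
  # one restart from the optimum to escape simplex collapse
  opt <- stats::optim(opt$par, objective, method = "Nelder-Mead",
                      control = list(reltol = ctrl$reltol, maxit = ctrl$maxit))
  structure(list(
    irf = gamma_irf(opt$par[1], exp(opt$par[2]), exp(opt$par[3])),
    b = stats::plogis(opt$par[4]),
    empirical = empirical,
    background_level = bg,
    score_value = opt$value,
    converged = opt$convergence == 0
  ), class = "irf_fit")
}

#' @export
print.irf_fit <- function(x, ...) {
  cat(sprintf("<irf_fit> t0 = %.4g ns, rho = %.4g, kappa = %.4g 1/ns, b = %.3g\n",
              x$irf$t0, x$irf$rho, x$irf$kappa, x$b))
  invisible(x)
}
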