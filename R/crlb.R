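# Real-argument dilogarithm and trilogarithm for z <= 0, the special
# functions appearing in the closed-form Fisher integrals. Strategy:
#  * |z| <= 0.25 (li2) / 0.5 (li3): direct power series
#  * z in (-1, -0.25): Landen transform (li2), duplication formula (li3)
#  * z < -1: inversion z -> 1/z
# All branches keep series arguments well inside the unit disk except the
# positive-argument series used by the li3 duplication, which is summed to
# convergence (arguments stay below 0.999; nearer one a zeta expansion is
# used). Accuracy ~1e-15 relative, verified against multiprecision values.

.zeta3 <- 1.2020569031595942854

li_series <- function(z, s, tol = 1e-18) {
  if (z == 0) return(0)
  kmax <- min(1e5, max(30, ceiling(log(tol) / log(abs(z)))))
  k <- seq_len(kmax)
  sum(z^k / k^s)
}

li2_real <- function(x) {
  vapply(x, function(z) {
    if (z > 0) stop("li2_real: argument must be <= 0", call. = FALSE)
    if (z == 0) return(0)
    if (z >= -0.25) return(li_series(z, 2))
    if (z > -1) {
      y <- z / (z - 1)                       # in (0.2, 0.5)
      return(-li_series(y, 2) - log1p(-z)^2 / 2)
    }
    if (z == -1) return(-pi^2 / 12)
    # z < -1: inversion
    -pi^2 / 6 - log(-z)^2 / 2 - li2_real(1 / z)
  }, numeric(1))
}

li3_pos <- function(z) {
  # z in (0, 1]
  if (z >= 1) return(.zeta3)
  if (z <= 0.999) return(li_series(z, 3))
  mu <- -log(z)
  .zeta3 - pi^2 * mu / 6 + mu^2 * (3 - 2 * log(mu)) / 4 + mu^3 / 12 -
    mu^4 / 288
}

li3_real <- function(x) {
  vapply(x, function(z) {
    if (z > 0) stop("li3_real: argument must be <= 0", call. = FALSE)
    if (z == 0) return(0)
    if (z >= -0.5) return(li_series(z, 3))
    if (z > -1) return(li3_pos(z^2) / 4 - li3_pos(-z))
    if (z == -1) return(-0.75 * .zeta3)
    li3_real(1 / z) - log(-z)^3 / 6 - pi^2 * log(-z) / 6
  }, numeric(1))
}

# Dimensionless Fisher entries for the mono-exponential decay with constant
# background and repetition period T, theta = (tau, b):
#   I_tautau = N * i_tt / tau^2,  I_taub = N * i_tb / tau,  I_bb = N * i_bb
# Derived by reducing the Fisher integral (substitution u = exp(-t/tau)) to
# incomplete-gamma and Fermi-Dirac-type integrals with polylogarithmic
# antiderivatives.
fisher_dimless_closed <- function(chi, b) {
  e <- exp(-chi)
  Z <- -expm1(-chi)
  a <- chi * e / Z
  E0 <- Z
  E1 <- 1 - (1 + chi) * e
  E2 <- 2 - (chi^2 + 2 * chi + 2) * e
  if (b == 0) {
    i_tt <- (E2 + 2 * (a - 1) * E1 + (a - 1)^2 * E0) / Z
    i_tb <- (chi^2 / 2 + (a - 1) * chi) / chi - (E1 + (a - 1) * E0) / Z
    i_bb <- (exp(chi) - 2 + e) / chi^2 - 1
    return(list(i_tt = i_tt, i_tb = i_tb, i_bb = i_bb))
  }
  alpha <- (1 - b) / Z
  beta <- b / chi
  cc <- alpha / beta
  y0 <- -cc
  y1 <- -cc * e
  l1_0 <- log1p(cc)
  l1_1 <- log1p(cc * e)
  li2_y0 <- li2_real(y0); li2_y1 <- li2_real(y1)
  li3_y0 <- li3_real(y0); li3_y1 <- li3_real(y1)
  # D_k = J_k - beta * F_k (cancellation-free forms)
  D0 <- l1_0 - l1_1
  D1 <- -chi * l1_1 + li2_y1 - li2_y0
  D2 <- -chi^2 * l1_1 + 2 * chi * li2_y1 + 2 * li3_y1 - 2 * li3_y0
  F0 <- (chi + l1_1 - l1_0) / beta
  G0 <- D0 / alpha; G1 <- D1 / alpha; G2 <- D2 / alpha
  H0 <- E0 / alpha - beta * G0 / alpha
  H1 <- E1 / alpha - beta * G1 / alpha
  H2 <- E2 / alpha - beta * G2 / alpha
  list(
    i_tt = alpha^2 * (H2 + 2 * (a - 1) * H1 + (a - 1)^2 * H0),
    i_tb = alpha * ((G1 + (a - 1) * G0) / chi - (H1 + (a - 1) * H0) / Z),
    i_bb = F0 / chi^2 - 2 * G0 / (chi * Z) + H0 / Z^2
  )
}

fisher_dimless_quadrature <- function(chi, b, rel.tol = 1e-9) {
  # Work in x = t/tau on [0, chi]; g(u) = (1-b) u / Z + b / chi, u = exp(-x)
  Z <- -expm1(-chi)
  a <- chi * exp(-chi) / Z
  g <- function(x) (1 - b) * exp(-x) / Z + b / chi
  dg_t <- function(x) (1 - b) * exp(-x) * (x - 1 + a) / Z   # tau * dp/dtau
  dg_b <- function(x) 1 / chi - exp(-x) / Z                 # dp/db
  quad <- function(f) {
    brk <- unique(pmin(chi, c(0, 2, 10, 50, chi)))
    s <- 0
    for (i in seq_len(length(brk) - 1)) {
      s <- s + stats::integrate(f, brk[i], brk[i + 1], rel.tol = rel.tol,
                                subdivisions = 400L)$value
    }
    s
  }
  list(
    i_tt = quad(function(x) dg_t(x)^2 / g(x)),
    i_tb = quad(function(x) dg_t(x) * dg_b(x) / g(x)),
    i_bb = quad(function(x) dg_b(x)^2 / g(x))
  )
}

#' Fisher information matrix for the lifetime and background
#'
#' Fisher information of `N` photon arrival times under the
#' mono-exponential-plus-background model with repetition period `T`, for
#' the parameter vector `theta = (tau, b)`. Entries scale linearly with `N`.
#'
#' `method = "closed_form"` evaluates analytically reduced integrals
#' (elementary functions plus di-/trilogarithms); `"quadrature"` evaluates
#' the defining integrals by adaptive quadrature (relative tolerance 1e-9)
#' and serves as an independent numerical oracle.
#'
#' @param tau Lifetime in ns (> 0).
#' @param b Background fraction in `[0, 1)`.
#' @param N Expected number of photons (> 0).
#' @param T Repetition period in ns (> 0).
#' @param method `"closed_form"` or `"quadrature"`.
#' @return A 2x2 symmetric matrix with dimnames `c("tau", "b")`, of class
#'   `fisher_matrix`, with attributes `N` and `T`.
#' @export
fisher_matrix <- function(tau, b, N, T, method = c("closed_form", "quadrature")) {
  method <- match.arg(method)
  stopifnot(tau > 0, N > 0, T > 0)
  if (b < 0 || b >= 1) {
    if (isTRUE(all.equal(b, 1)) || b >= 1)
      stop("degenerate information: b = 1 carries no lifetime information",
           call. = FALSE)
    stop("invalid parameter: b must lie in [0, 1)", call. = FALSE)
  }
  chi <- T / tau
  d <- switch(method,
              closed_form = fisher_dimless_closed(chi, b),
              quadrature = fisher_dimless_quadrature(chi, b))
  m <- matrix(c(N * d$i_tt / tau^2, N * d$i_tb / tau,
                N * d$i_tb / tau, N * d$i_bb),
              2, 2, dimnames = list(c("tau", "b"), c("tau", "b")))
  structure(m, class = c("fisher_matrix", class(m)), N = N, T = T)
}

#' Cramer-Rao lower bound on the lifetime standard deviation
#'
#' Minimum standard deviation achievable by an unbiased lifetime estimator
#' from `N` photons under the mono-exponential decay model with background
#' fraction `b` and repetition period `T`.
#'
#' When `background_known = FALSE` (the usual TCSPC situation) the bound is
#' the `tau` diagonal element of the inverse Fisher matrix for
#' `theta = (tau, b)`; when the background level is known in advance it is
#' `1 / sqrt(I_tautau)`, which is never larger.
#'
#' @inheritParams fisher_matrix
#' @param background_known Is the background fraction known a priori?
#' @param method Passed to [fisher_matrix()].
#' @return The bound `sigma_tau` in ns. Vectorized over `tau`, `b`, `N`, `T`.
#' @examples
#' crlb_sigma_tau(tau = 2, b = 0, N = 400, T = 1e9)  # ~ tau / sqrt(N) = 0.1
#' @export
crlb_sigma_tau <- function(tau, b, N, T, background_known = FALSE,
                           method = c("closed_form", "quadrature")) {
  method <- match.arg(method)
  n <- max(length(tau), length(b), length(N), length(T))
  tau <- rep_len(tau, n); b <- rep_len(b, n)
  N <- rep_len(N, n); T <- rep_len(T, n)
  vapply(seq_len(n), function(i) {
    if (b[i] >= 1)
      stop("degenerate information: b = 1 carries no lifetime information",
           call. = FALSE)
    chi <- T[i] / tau[i]
    d <- switch(method,
                closed_form = fisher_dimless_closed(chi, b[i]),
                quadrature = fisher_dimless_quadrature(chi, b[i]))
    denom <- if (background_known) d$i_tt else {
      corr <- if (is.finite(d$i_bb) && d$i_bb > 0) d$i_tb^2 / d$i_bb else 0
      d$i_tt - corr
    }
    if (!is.finite(denom) || denom <= 0)
      stop("non-identifiable: singular Fisher matrix", call. = FALSE)
    tau[i] / sqrt(N[i] * denom)
  }, numeric(1))
}

#' Closed-form limiting cases of the lifetime CRLB
#'
#' Limiting variances of the lifetime estimate:
#' \describe{
#'   \item{`poisson`}{infinitely long repetition period: only the
#'     `N (1 - b)` signal photons carry lifetime information,
#'     `sigma_tau^2 = tau^2 / (N (1 - b))`}
#'   \item{`zero_bg_known`}{finite `T = chi * tau`, background known to be
#'     zero}
#'   \item{`zero_bg_unknown`}{finite `T`, background zero but estimated as a
#'     free parameter; always at least as large as `zero_bg_known`}
#' }
#' Both finite-`T` limits approach `tau^2 / N` as `chi -> Inf`.
#'
#' @param tau Lifetime in ns.
#' @param N Number of photons.
#' @param which Which limit to evaluate.
#' @param b Background fraction (for `which = "poisson"`).
#' @param chi Ratio `T / tau` (for the finite-`T` limits).
#' @return The variance `sigma_tau^2` in ns^2.
#' @export
crlb_limit <- function(tau, N, which = c("poisson", "zero_bg_known",
                                         "zero_bg_unknown"),
                       b = 0, chi = NULL) {
  which <- match.arg(which)
  stopifnot(tau > 0, N > 0)
  if (which == "poisson") {
    if (any(b >= 1)) stop("b must be < 1", call. = FALSE)
    return(tau^2 / (N * (1 - b)))
  }
  if (is.null(chi)) stop("chi = T / tau is required for finite-T limits",
                         call. = FALSE)
  stopifnot(chi > 0)
  if (which == "zero_bg_known") {
    e <- exp(-chi)
    # tau^2/N * 2(1 - cosh chi) / (2 + chi^2 - 2 cosh chi), written in a
    # form stable for large chi (numerator and denominator scaled by e^-chi)
    return(tau^2 / N * (2 * e - 1 - e^2) / ((2 + chi^2) * e - 1 - e^2))
  }
  # zero background, background estimated: tau-diagonal of the inverse
  # 2x2 Fisher matrix evaluated at b = 0
  vapply(seq_along(chi), function(i) {
    d <- fisher_dimless_closed(chi[i], 0)
    corr <- if (is.finite(d$i_bb) && d$i_bb > 0) d$i_tb^2 / d$i_bb else 0
    tau^2 / (N * (d$i_tt - corr))
  }, numeric(1))
}
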