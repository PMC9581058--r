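#' Parametric instrument response function (shifted Gamma)
#'
#' The IRF is modeled as a Gamma density shifted to start at `t0`: zero for
#' `t <= t0`, proportional to `(t - t0)^(rho - 1) * exp(-kappa * (t - t0))`
#' afterwards. The shifted Gamma captures the typical asymmetry of measured
#' IRFs (fast rise, slower fall).
#'
#' @param t0 Start time of the peak in ns (`0 <= t0 < T` on the grids it is
#'   evaluated on).
#' @param rho Shape parameter (> 0).
#' @param kappa Rate parameter in 1/ns (> 0).
#' @return An object of class `gamma_irf`.
#' @export
gamma_irf <- function(t0, rho, kappa) {
  if (!is.finite(rho) || rho <= 0 || !is.finite(kappa) || kappa <= 0)
    stop("invalid parameter: rho and kappa must be positive", call. = FALSE)
  if (!is.finite(t0) || t0 < 0)
    stop("invalid parameter: t0 must be non-negative", call. = FALSE)
  structure(list(t0 = t0, rho = rho, kappa = kappa), class = "gamma_irf")
}

#' @export
print.gamma_irf <- function(x, ...) {
  cat(sprintf("<gamma_irf> t0 = %g ns, rho = %g, kappa = %g 1/ns\n",
              x$t0, x$rho, x$kappa))
  invisible(x)
}

#' Empirical (tabulated) instrument response function
#'
#' A non-negative per-bin curve, normalized to sum to one.
#'
#' @param curve Non-negative vector of length `grid$K`.
#' @param grid A [tcspc_grid()].
#' @return An object of class `empirical_irf` with fields `curve` and `grid`.
#' @export
empirical_irf <- function(curve, grid) {
  stopifnot(is_tcspc_grid(grid))
  if (length(curve) != grid$K)
    stop("grid mismatch: length(curve) != grid$K", call. = FALSE)
  if (any(!is.finite(curve)) || any(curve < 0))
    stop("invalid IRF: curve must be finite and non-negative", call. = FALSE)
  s <- sum(curve)
  if (s <= 0) stop("invalid IRF: curve sums to zero", call. = FALSE)
  structure(list(curve = curve / s, grid = grid), class = "empirical_irf")
}

#' Evaluate a shifted-Gamma IRF on a grid
#'
#' @param irf A [gamma_irf()].
#' @param grid A [tcspc_grid()].
#' @return An [empirical_irf()] (normalized curve, zero for `t <= t0`).
#' @export
gamma_irf_curve <- function(irf, grid) {
  stopifnot(inherits(irf, "gamma_irf"), is_tcspc_grid(grid))
  if (irf$t0 >= grid$period)
    stop("invalid parameter: t0 must lie within the repetition period",
         call. = FALSE)
  t_i <- grid$bin_start_times
  q <- numeric(grid$K)
  pos <- t_i > irf$t0
  dt <- t_i[pos] - irf$t0
  q[pos] <- grid$delta_t * irf$kappa^irf$rho * dt^(irf$rho - 1) *
    exp(-irf$kappa * dt) / gamma(irf$rho)
  empirical_irf(q, grid)
}

irf_on_grid <- function(irf, grid) {
  if (inherits(irf, "gamma_irf")) gamma_irf_curve(irf, grid)
  else if (inherits(irf, "empirical_irf")) {
    if (irf$grid$K != grid$K)
      stop("grid mismatch between IRF and model grid", call. = FALSE)
    irf
  } else stop("irf must be a gamma_irf or empirical_irf", call. = FALSE)
}

#' Full width at half maximum of an IRF
#'
#' Width of a unimodal curve at half its peak height, with linear
#' interpolation between bins on both flanks.
#'
#' @param irf An [empirical_irf()] or [gamma_irf()].
#' @param grid Grid on which to evaluate a parametric IRF; defaults to the
#'   empirical IRF's own grid.
#' @return Width in ns.
#' @export
irf_fwhm <- function(irf, grid = NULL) {
  if (inherits(irf, "gamma_irf")) {
    if (is.null(grid)) stop("a grid is required for a parametric IRF", call. = FALSE)
    irf <- gamma_irf_curve(irf, grid)
  }
  q <- irf$curve
  tc <- bin_centers(irf$grid)
  pk <- which.max(q)
  if (max(q) <= 0 || diff(range(q)) <= 1e-12 * max(abs(q)))
    stop("undefined width: curve is flat", call. = FALSE)
  half <- q[pk] / 2
  cross <- function(i0, i1) {
    # linear interpolation of the time where q crosses `half` between bins
    t0 <- tc[i0]; t1 <- tc[i1]; q0 <- q[i0]; q1 <- q[i1]
    t0 + (half - q0) * (t1 - t0) / (q1 - q0)
  }
  left <- {
    i <- pk
    while (i > 1 && q[i] > half) i <- i - 1
    if (q[i] > half) tc[1] - irf$grid$delta_t / 2 else cross(i, i + 1)
  }
  right <- {
    i <- pk
    while (i < length(q) && q[i] > half) i <- i + 1
    if (q[i] > half) tc[length(q)] + irf$grid$delta_t / 2 else cross(i - 1, i)
  }
  right - left
}

#' Circular convolution with an IRF
#'
#' Discrete circular convolution of a per-bin model vector with a normalized
#' IRF curve, implemented via FFT. The convolution wraps at the end of the
#' grid, mirroring the periodic wrap-around of the decay in the repetition
#' period. Bin 1 of the IRF is aligned with bin 1 of the model (zero shift);
#' any time shift of the IRF lives in its own curve (e.g. the `t0` of a
#' [gamma_irf()]). Because the IRF sums to one, the convolution preserves
#' the vector sum.
#'
#' @param x Per-bin model vector (probabilities or expected counts).
#' @param irf An [empirical_irf()] (or [gamma_irf()], evaluated on `grid`).
#' @param grid Grid of `x`; defaults to the empirical IRF's grid.
#' @return The convolved vector, same length as `x`.
#' @export
convolve_with_irf <- function(x, irf, grid = NULL) {
  if (inherits(irf, "gamma_irf")) {
    if (is.null(grid)) stop("a grid is required for a parametric IRF", call. = FALSE)
    irf <- gamma_irf_curve(irf, grid)
  }
  q <- irf$curve
  if (length(x) != length(q))
    stop("grid mismatch: model vector and IRF have different lengths", call. = FALSE)
  out <- Re(stats::fft(stats::fft(x) * stats::fft(q), inverse = TRUE)) / length(x)
  # FFT round-off can leave tiny negative values in near-zero bins
  pmax(out, 0) * (sum(x) / max(sum(pmax(out, 0)), .Machine$double.xmin))
}
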