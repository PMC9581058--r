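#' Parameters of the mono-exponential decay model
#'
#' The model describes the distribution of photon arrival times within one
#' repetition period: a fraction `1 - b` of photons follows an exponential
#' decay with lifetime `tau` (wrapped in the period `T`), the remaining
#' fraction `b` is uniform background. `n_hat` is the expected total number
#' of detected photons.
#'
#' @param tau Fluorescence lifetime in ns (> 0).
#' @param b Background fraction in `[0, 1]`.
#' @param n_hat Expected total photon count (> 0); may be `NA` when only the
#'   arrival-time distribution is needed.
#' @return An object of class `decay_params`.
#' @examples
#' decay_params(tau = 2, b = 0.2, n_hat = 2000)
#' @export
decay_params <- function(tau, b, n_hat = NA_real_) {
  if (!is.numeric(tau) || length(tau) != 1 || !is.finite(tau) || tau <= 0)
    stop("invalid parameter: tau must be a single positive number", call. = FALSE)
  if (!is.numeric(b) || length(b) != 1 || !is.finite(b) || b < 0 || b > 1)
    stop("invalid parameter: b must lie in [0, 1]", call. = FALSE)
  if (!is.na(n_hat) && (!is.numeric(n_hat) || n_hat <= 0))
    stop("invalid parameter: n_hat must be positive", call. = FALSE)
  structure(list(tau = tau, b = b, n_hat = as.numeric(n_hat)),
            class = "decay_params")
}

#' @export
print.decay_params <- function(x, ...) {
  cat(sprintf("<decay_params> tau = %g ns, b = %g, n_hat = %g\n",
              x$tau, x$b, x$n_hat))
  invisible(x)
}

#' Per-bin photon detection probabilities
#'
#' Probability for a detected photon to fall into each TCSPC bin under the
#' mono-exponential decay model with constant background.
#'
#' Two discretization modes are provided. `"integrated"` (default) uses the
#' exact integral of the arrival-time density over each bin, with the decay
#' part normalized over the grid so that the probabilities sum to one by
#' construction. `"point"` samples the arrival-time density at the channel
#' center and multiplies by the bin width; its sum then deviates from one
#' only at second order in `delta_t / tau`, which is negligible for the
#' usual `delta_t << tau`.
#'
#' @param params A [decay_params()] object.
#' @param grid A [tcspc_grid()].
#' @param mode `"integrated"` or `"point"`.
#' @return Numeric vector of length `grid$K`, non-negative.
#' @examples
#' g <- tcspc_grid(0.016, 25)
#' p <- bin_probabilities(decay_params(2, 0.2), g)
#' sum(p)  # exactly 1
#' @export
bin_probabilities <- function(params, grid, mode = c("integrated", "point")) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "decay_params"), is_tcspc_grid(grid))
  tau <- params$tau; b <- params$b
  t_i <- grid$bin_start_times
  K <- grid$K
  if (mode == "integrated") {
    w <- exp(-t_i / tau) * (-expm1(-grid$delta_t / tau))
    w <- w / sum(w)
    (1 - b) * w + b / K
  } else {
    denom <- tau * (-expm1(-grid$period / tau))
    grid$delta_t * (1 - b) * exp(-(t_i + grid$delta_t / 2) / tau) / denom +
      b / K
  }
}

#' Expected counts per TCSPC bin
#'
#' Expectation value of the photon count in each bin:
#' `n_hat` times [bin_probabilities()].
#'
#' @inheritParams bin_probabilities
#' @return Numeric vector of expected counts of length `grid$K`.
#' @export
expected_counts <- function(params, grid, mode = c("integrated", "point")) {
  if (is.na(params$n_hat))
    stop("expected_counts() needs n_hat in the decay parameters", call. = FALSE)
  params$n_hat * bin_probabilities(params, grid, mode)
}

#' Keep only the tail of a decay curve
#'
#' Removes all bins before `t_cut` nanoseconds after the curve peak. Used for
#' tail fitting, where the initial part of a TCSPC histogram (the part shaped
#' by the instrument response function) is excluded so that the remaining
#' bins follow the pure exponential-plus-background model. For batches of
#' single-molecule histograms the peak is conventionally located on the sum
#' of all decays; pass that index via `peak_index`.
#'
#' Bins with `t >= t_peak + t_cut` are kept; earlier bins (including any bins
#' before the peak) are dropped. When `renormalize = TRUE` the shortened
#' vector is rescaled to sum to one, as appropriate for probability patterns.
#'
#' @param x Per-bin vector (counts, probabilities or expectations).
#' @param grid The [tcspc_grid()] of `x`.
#' @param t_cut Cut-off in ns after the peak (>= 0).
#' @param peak_index Index of the reference peak; defaults to `which.max(x)`.
#' @param renormalize Rescale the kept bins to sum to one.
#' @return List with `values` (shortened vector), `grid` (shortened grid,
#'   times rebased to start at 0) and `idx` (kept indices in the input grid).
#' @export
truncate_tail <- function(x, grid, t_cut, peak_index = which.max(x),
                          renormalize = FALSE) {
  stopifnot(is_tcspc_grid(grid), length(x) == grid$K, t_cut >= 0)
  first <- peak_index + as.integer(ceiling(t_cut / grid$delta_t - 1e-9))
  if (first > grid$K)
    stop("empty selection: t_cut lies beyond the last bin", call. = FALSE)
  idx <- first:grid$K
  v <- x[idx]
  if (renormalize) {
    s <- sum(v)
    if (s <= 0) stop("cannot renormalize: tail sums to zero", call. = FALSE)
    v <- v / s
  }
  list(values = v, grid = subset_grid(grid, idx), idx = idx)
}
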