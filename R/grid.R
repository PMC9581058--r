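#' TCSPC time axis
#'
#' Constructs the discrete time axis of a TCSPC measurement: `K` bins of
#' width `delta_t` (ns) tiling the laser repetition period `period` (ns).
#' Bin `i` covers the half-open interval `[t_i, t_i + delta_t)` with
#' `t_1 = 0`. Because `period / delta_t` need not be an integer, the default
#' number of bins is `floor(period / delta_t)`; the residual interval is
#' folded into the circular convolution period rather than tiled.
#'
#' @param delta_t Bin width in ns. Must be positive.
#' @param period Laser repetition period `T` in ns.
#' @param K Number of bins. Defaults to `floor(period / delta_t)`.
#'
#' @return An object of class `tcspc_grid` with fields `K`, `delta_t`,
#'   `period` and `bin_start_times` (left bin edges, ns).
#' @examples
#' g <- tcspc_grid(delta_t = 0.016, period = 25)
#' g$K
#' @export
tcspc_grid <- function(delta_t, period, K = NULL) {
  stopifnot(is.numeric(delta_t), length(delta_t) == 1, delta_t > 0,
            is.numeric(period), length(period) == 1, period > 0)
  if (is.null(K)) K <- floor(period / delta_t + 1e-9)
  K <- as.integer(K)
  if (K < 4) stop("a TCSPC grid needs at least 4 bins (K >= 4)", call. = FALSE)
  if (K * delta_t > period * (1 + 1e-9))
    stop("grid overruns the repetition period: K * delta_t must be <= period",
         call. = FALSE)
  structure(
    list(K = K, delta_t = delta_t, period = period,
         bin_start_times = (seq_len(K) - 1) * delta_t),
    class = "tcspc_grid"
  )
}

#' @export
print.tcspc_grid <- function(x, ...) {
  cat(sprintf("<tcspc_grid> K = %d bins, delta_t = %g ns, period = %g ns\n",
              x$K, x$delta_t, x$period))
  invisible(x)
}

is_tcspc_grid <- function(x) inherits(x, "tcspc_grid")

bin_centers <- function(grid) grid$bin_start_times + grid$delta_t / 2

# Contiguous sub-grid keeping bins idx (a contiguous, increasing index run).
# Times are rebased so the first kept bin starts at 0; the repetition period
# is retained because the decay still wraps in the full period.
subset_grid <- function(grid, idx) {
  stopifnot(is_tcspc_grid(grid), length(idx) >= 1)
  g <- grid
  g$K <- length(idx)
  g$bin_start_times <- grid$bin_start_times[idx] - grid$bin_start_times[idx[1]]
  if (g$K < 4)
    stop("sub-grid has fewer than 4 bins", call. = FALSE)
  g
}

#' Merge adjacent TCSPC bins
#'
#' Groups `factor` adjacent bins into one, reducing the time resolution.
#' Any remainder bins that do not fill a complete group are dropped.
#'
#' @param grid A [tcspc_grid()].
#' @param factor Integer rebinning factor (>= 1).
#' @return A coarser `tcspc_grid`.
#' @export
rebin_grid <- function(grid, factor) {
  stopifnot(is_tcspc_grid(grid), factor >= 1)
  factor <- as.integer(factor)
  if (factor == 1L) return(grid)
  K2 <- grid$K %/% factor
  if (K2 < 4) stop("rebinning would leave fewer than 4 bins", call. = FALSE)
  g <- grid
  g$K <- K2
  g$delta_t <- grid$delta_t * factor
  g$bin_start_times <- grid$bin_start_times[1] +
    (seq_len(K2) - 1) * g$delta_t
  g
}

# Sum counts (or any per-bin vector) over groups of `factor` adjacent bins,
# dropping remainder bins; pairs with rebin_grid().
rebin_values <- function(x, factor) {
  factor <- as.integer(factor)
  if (factor == 1L) return(x)
  K2 <- length(x) %/% factor
  colSums(matrix(x[seq_len(K2 * factor)], nrow = factor))
}
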