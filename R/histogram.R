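#' A TCSPC histogram
#'
#' Observed photon counts per time bin on a [tcspc_grid()].
#'
#' @param counts Non-negative integer vector of length `grid$K`.
#' @param grid A [tcspc_grid()].
#' @return An object of class `tcspc_histogram` with fields `counts`,
#'   `grid` and `n` (total photons).
#' @export
tcspc_histogram <- function(counts, grid) {
  stopifnot(is_tcspc_grid(grid))
  if (length(counts) != grid$K)
    stop("grid mismatch: length(counts) != grid$K", call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("invalid input: counts must be finite and non-negative", call. = FALSE)
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("invalid input: counts must be integers", call. = FALSE)
  counts <- as.numeric(round(counts))
  structure(list(counts = counts, grid = grid, n = sum(counts)),
            class = "tcspc_histogram")
}

#' @export
print.tcspc_histogram <- function(x, ...) {
  cat(sprintf("<tcspc_histogram> %d bins, %g photons, delta_t = %g ns\n",
              x$grid$K, x$n, x$grid$delta_t))
  invisible(x)
}

#' Rebin a TCSPC histogram
#'
#' @param hist A [tcspc_histogram()].
#' @param factor Integer rebinning factor.
#' @return A `tcspc_histogram` on the coarser grid (remainder bins dropped).
#' @export
rebin_histogram <- function(hist, factor) {
  stopifnot(inherits(hist, "tcspc_histogram"))
  tcspc_histogram(rebin_values(hist$counts, factor),
                  rebin_grid(hist$grid, factor))
}

#' Moment (mean arrival time) lifetime estimate
#'
#' The photon-count-weighted mean of the bin center times. This direct
#' estimator equals the lifetime only for zero background and a repetition
#' period much longer than the lifetime; with background it is biased toward
#' `T/2`, and with finite `T` toward smaller values. It is nonetheless a
#' useful rough initializer.
#'
#' @param hist A [tcspc_histogram()].
#' @return Lifetime estimate in ns.
#' @export
moment_lifetime <- function(hist) {
  stopifnot(inherits(hist, "tcspc_histogram"))
  if (hist$n < 1) stop("no photons in histogram", call. = FALSE)
  sum(hist$counts * bin_centers(hist$grid)) / hist$n
}
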