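#' Build a pattern library from reference decays
#'
#' Normalizes reference decay curves (one column per species) to unit sum
#' and stores their elementwise logarithms, so that Poisson negative
#' log-likelihoods against every pattern reduce to one matrix
#' multiplication ([neg_loglik_matrix()]). Zero bins are floored at
#' `floor_eps` before the logarithm: impossible bins then stay finite but
#' are effectively decisive against a pattern.
#'
#' @param x Numeric `K x S` matrix of reference decays (counts, expectations
#'   or probabilities as columns), or a single vector.
#' @param labels Optional species labels: a character vector of length `S`
#'   or a data frame with `S` rows (e.g. the `(tau, b)` coordinates of a
#'   model grid).
#' @param floor_eps Floor applied to zero pattern bins before the log.
#' @return An object of class `pattern_library` with fields `patterns`
#'   (columns summing to one), `log_patterns`, `labels`, `K`, `S`.
#' @export
pattern_library <- function(x, labels = NULL, floor_eps = 1e-12) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  stopifnot(is.matrix(x), floor_eps > 0)
  if (any(x < 0) || any(!is.finite(x)))
    stop("invalid pattern: negative or non-finite values", call. = FALSE)
  cs <- colSums(x)
  if (any(cs <= 0))
    stop("invalid pattern: a reference column is all zero", call. = FALSE)
  p <- sweep(x, 2, cs, "/")
  if (is.null(labels)) labels <- as.character(seq_len(ncol(p)))
  structure(list(
    patterns = p,
    log_patterns = log(pmax(p, floor_eps)),
    labels = labels,
    K = nrow(p), S = ncol(p), floor_eps = floor_eps
  ), class = "pattern_library")
}

#' @export
print.pattern_library <- function(x, ...) {
  cat(sprintf("<pattern_library> %d bins x %d patterns\n", x$K, x$S))
  invisible(x)
}

# Model-decay pattern matrix on a (tau, b) grid. Columns are ordered with
# tau varying fastest within each background value. Optional IRF
# reconvolution, tail-window truncation (window_idx on the full grid,
# renormalized) and rebinning, applied in that order -- exactly the
# processing applied to the data they are matched against.
decay_pattern_matrix <- function(tau_grid, b_grid, grid,
                                 mode = "integrated", irf = NULL,
                                 window_idx = NULL, rebin = 1L) {
  stopifnot(length(tau_grid) >= 1, length(b_grid) >= 1)
  t_i <- grid$bin_start_times
  K <- grid$K
  W <- if (mode == "integrated") {
    w <- exp(outer(t_i, -1 / tau_grid)) *
      rep(-expm1(-grid$delta_t / tau_grid), each = K)
    sweep(w, 2, colSums(w), "/")
  } else {
    w <- exp(outer(t_i + grid$delta_t / 2, -1 / tau_grid)) *
      rep(grid$delta_t / (tau_grid * (-expm1(-grid$period / tau_grid))), each = K)
    w
  }
  if (!is.null(irf)) {
    q <- irf_on_grid(irf, grid)$curve
    fq <- stats::fft(q)
    W <- Re(stats::mvfft(stats::mvfft(W) * fq, inverse = TRUE)) / K
    W <- pmax(W, 0)
    W <- sweep(W, 2, colSums(W), "/")
  }
  nt <- length(tau_grid)
  out <- matrix(0, nrow = if (is.null(window_idx)) K else length(window_idx),
                ncol = nt * length(b_grid))
  for (ib in seq_along(b_grid)) {
    P <- (1 - b_grid[ib]) * W + b_grid[ib] / K
    if (!is.null(window_idx)) {
      P <- P[window_idx, , drop = FALSE]
      P <- sweep(P, 2, colSums(P), "/")
    }
    out[, (ib - 1) * nt + seq_len(nt)] <- P
  }
  if (rebin > 1L) {
    out <- rebin_matrix_rows(out, rebin)
  }
  # normalize columns so patterns are comparable likelihood models even in
  # point mode or after rebinning drops remainder bins
  sweep(out, 2, colSums(out), "/")
}

# Sum groups of `factor` adjacent rows of a matrix (vectorized rebinning of
# all pattern columns at once); remainder rows are dropped.
rebin_matrix_rows <- function(x, factor) {
  factor <- as.integer(factor)
  if (factor == 1L) return(x)
  K2 <- nrow(x) %/% factor
  S <- ncol(x)
  matrix(colSums(matrix(x[seq_len(K2 * factor), , drop = FALSE],
                        nrow = factor)), nrow = K2, ncol = S)
}

#' Model-grid pattern library
#'
#' Builds a [pattern_library()] of mono-exponential decay patterns on a
#' `(tau, b)` grid, optionally reconvolved with an IRF, truncated to a tail
#' window and rebinned -- mirroring the processing of the histograms the
#' library is matched against. Used for fast grid-search fitting
#' ([grid_fit()]) and for initial fit values.
#'
#' @param tau_grid,b_grid Lifetime (ns) and background-fraction grids.
#' @param grid The [tcspc_grid()] of the full-resolution histograms.
#' @param mode See [bin_probabilities()].
#' @param irf Optional IRF for reconvolution.
#' @param window_idx Optional indices (on the full grid) of a tail window;
#'   patterns are truncated there and renormalized.
#' @param rebin Integer rebinning factor applied after truncation.
#' @param floor_eps Passed to [pattern_library()].
#' @return A `pattern_library` whose `labels` is a tibble with columns
#'   `tau` and `b`.
#' @export
decay_pattern_library <- function(tau_grid, b_grid, grid,
                                  mode = "integrated", irf = NULL,
                                  window_idx = NULL, rebin = 1L,
                                  floor_eps = 1e-12) {
  P <- decay_pattern_matrix(tau_grid, b_grid, grid, mode, irf, window_idx,
                            rebin)
  labels <- tidyr::expand_grid(b = b_grid, tau = tau_grid)[, c("tau", "b")]
  pattern_library(P, labels = labels, floor_eps = floor_eps)
}

#' Negative log-likelihood matrix of histograms against a pattern library
#'
#' For `J` histograms (rows of `M`) and `S` patterns, computes the `J x S`
#' matrix `Lambda = -M %*% log(P)`, whose entry `(j, alpha)` is the Poisson
#' negative log-likelihood of histogram `j` under pattern `alpha` (up to
#' pattern-independent constants).
#'
#' @param M `J x K` matrix of histogram counts (a single histogram may be
#'   passed as a vector).
#' @param library A [pattern_library()] with matching `K`.
#' @return The `J x S` matrix `Lambda`.
#' @export
neg_loglik_matrix <- function(M, library) {
  stopifnot(inherits(library, "pattern_library"))
  if (is.vector(M)) M <- matrix(M, nrow = 1)
  if (ncol(M) != library$K)
    stop("grid mismatch: histograms and patterns differ in bin count",
         call. = FALSE)
  -M %*% library$log_patterns
}

#' Most likely pattern per histogram
#'
#' Row-wise argmin of the negative log-likelihood matrix; ties are broken
#' deterministically to the lowest column index.
#'
#' @param lambda `J x S` matrix from [neg_loglik_matrix()].
#' @return Integer vector of best pattern indices, length `J`.
#' @export
classify_patterns <- function(lambda) {
  if (is.vector(lambda)) lambda <- matrix(lambda, nrow = 1)
  max.col(-lambda, ties.method = "first")
}

#' Posterior species probabilities
#'
#' Converts negative log-likelihoods into relative probabilities
#' `f = exp(-lambda) / sum(exp(-lambda))` per histogram (a row-wise
#' softmin). Assuming equal priors this is the posterior probability of a
#' Bayesian model comparison. The row minimum is subtracted before
#' exponentiation, which leaves `f` unchanged but avoids overflow at large
#' photon numbers.
#'
#' @param lambda `J x S` matrix from [neg_loglik_matrix()].
#' @return `J x S` matrix of posteriors; every row sums to one.
#' @export
pattern_posterior <- function(lambda) {
  if (is.vector(lambda)) lambda <- matrix(lambda, nrow = 1)
  e <- exp(-(lambda - apply(lambda, 1, min)))
  sweep(e, 1, rowSums(e), "/")
}

#' Classify histograms against a pattern library
#'
#' Convenience wrapper chaining [neg_loglik_matrix()], [classify_patterns()]
#' and [pattern_posterior()], with optional rejection of molecules that
#' cannot be assigned with high confidence.
#'
#' @param M `J x K` count matrix.
#' @param library A [pattern_library()].
#' @param min_posterior Optional confidence threshold: molecules whose
#'   largest posterior falls below it are flagged `accepted = FALSE`.
#' @return A tibble with `id`, `best` (pattern index), `label` (if the
#'   library labels are a vector), `f_max` and `accepted`, plus one
#'   posterior column per pattern (`f_1`, ...) when `S <= 10`.
#' @export
classify_histograms <- function(M, library, min_posterior = 0.9) {
  if (is.vector(M)) M <- matrix(M, nrow = 1)
  lam <- neg_loglik_matrix(M, library)
  best <- classify_patterns(lam)
  f <- pattern_posterior(lam)
  f_max <- f[cbind(seq_len(nrow(f)), best)]
  out <- tibble::tibble(
    id = seq_len(nrow(M)),
    best = best,
    f_max = f_max,
    accepted = if (is.null(min_posterior)) TRUE else f_max >= min_posterior
  )
  if (is.atomic(library$labels)) out$label <- library$labels[best]
  if (library$S <= 10) {
    fp <- tibble::as_tibble(as.data.frame(f, optional = TRUE),
                            .name_repair = ~ paste0("f_", seq_len(library$S)))
    out <- dplyr::bind_cols(out, fp)
  }
  out
}

#' Grid-search lifetime fitting by pattern matching
#'
#' Maximum-likelihood estimation of `(tau, b)` restricted to a discrete
#' parameter grid, computed for many histograms at once via the pattern
#' matrix multiplication. The resolution is limited to the grid spacing,
#' which makes this ideal for initial values and for fast batch estimates.
#'
#' The patterns are processed exactly like the data: same optional IRF
#' reconvolution, same tail window (determined from the peak of the summed
#' decays plus `tail_cut`, with renormalization), same rebinning.
#'
#' @param counts `J x K` count matrix (or a single histogram vector).
#' @param grid The common [tcspc_grid()].
#' @param tau_grid,b_grid Parameter grids.
#' @param mode See [bin_probabilities()].
#' @param irf Optional IRF (reconvolution case).
#' @param tail_cut Optional tail cut-off in ns after the summed-decay peak
#'   (tail-fit case).
#' @param peak_index Peak reference for the tail window; defaults to the
#'   maximum of the summed decays.
#' @param rebin Integer factor: data and patterns are rebinned together
#'   before matching. Because summing Poisson bins stays Poisson, this
#'   coarsening is exact (it only discards the negligible information in
#'   the sub-bin structure) and greatly reduces the matrix size.
#' @param chunk Number of pattern columns processed per block (memory bound).
#' @return A tibble with one row per histogram: `tau_hat`, `b_hat`,
#'   `lambda_min`.
#' @export
grid_fit <- function(counts, grid, tau_grid, b_grid = seq(0, 0.9, length.out = 60),
                     mode = "integrated", irf = NULL, tail_cut = NULL,
                     peak_index = NULL, rebin = 1L, chunk = 4000L) {
  if (is.vector(counts)) counts <- matrix(counts, nrow = 1)
  stopifnot(ncol(counts) == grid$K)
  window_idx <- NULL
  M <- counts
  if (!is.null(tail_cut)) {
    peak <- peak_index %||% which.max(colSums(counts))
    tr <- truncate_tail(colSums(counts), grid, tail_cut, peak_index = peak)
    window_idx <- tr$idx
    M <- counts[, window_idx, drop = FALSE]
  }
  if (rebin > 1L) {
    M <- t(rebin_matrix_rows(t(M), rebin))
  }
  J <- nrow(M)
  nt <- length(tau_grid)
  best_val <- rep(Inf, J)
  best_idx <- rep(1L, J)
  # process the b-grid in blocks to bound the pattern-matrix memory
  bs <- max(1L, floor(chunk / nt))
  for (start in seq(1L, length(b_grid), by = bs)) {
    bb <- b_grid[start:min(start + bs - 1L, length(b_grid))]
    P <- decay_pattern_matrix(tau_grid, bb, grid, mode, irf, window_idx, rebin)
    am <- grid_argmin(M, log(pmax(P, 1e-12)))
    upd <- am$val < best_val
    best_val[upd] <- am$val[upd]
    best_idx[upd] <- (start - 1L) * nt + am$idx[upd]
  }
  ib <- (best_idx - 1L) %/% nt + 1L
  it <- (best_idx - 1L) %% nt + 1L
  tibble::tibble(tau_hat = tau_grid[it], b_hat = b_grid[ib],
                 lambda_min = best_val)
}

# Row-wise argmin of Lambda = -M %*% logP without materializing more than
# one block of Lambda at a time.
grid_argmin <- function(M, logP, block = 1e7) {
  J <- nrow(M)
  S <- ncol(logP)
  cs <- max(1L, min(S, floor(block / max(J, 1))))
  best_val <- rep(Inf, J)
  best_idx <- rep(1L, J)
  for (start in seq(1L, S, by = cs)) {
    cols <- start:min(start + cs - 1L, S)
    lam <- -M %*% logP[, cols, drop = FALSE]
    col <- max.col(-lam, ties.method = "first")
    val <- lam[cbind(seq_len(J), col)]
    upd <- val < best_val
    best_val[upd] <- val[upd]
    best_idx[upd] <- start - 1L + col[upd]
  }
  list(idx = best_idx, val = best_val)
}
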