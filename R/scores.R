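score_kinds <- c("lsq", "pearson", "neyman1", "neg_loglik", "poisson_deviance")

#' Score functions for TCSPC histogram fitting
#'
#' Evaluates one of five score functions comparing observed counts `m` with
#' a model:
#' \describe{
#'   \item{`lsq`}{unweighted least squares, `sum((mhat - m)^2)`}
#'   \item{`pearson`}{weighted least squares with the model expectation as
#'     variance estimate, `sum((mhat - m)^2 / mhat)`}
#'   \item{`neyman1`}{weighted least squares with the observed counts as
#'     variance estimate; zero denominators are replaced by one (the variant
#'     that skips zero-count bins is not offered because it destabilizes
#'     fits)}
#'   \item{`neg_loglik`}{negative log-likelihood of the Poisson/multinomial
#'     counts, `-sum(m * log(p))`, taking per-bin probabilities `p`}
#'   \item{`poisson_deviance`}{the likelihood-ratio deviance
#'     `2 * sum(m * log(m / mhat) - m + mhat)`}
#' }
#' `neg_loglik` uses probabilities; all others use expected counts.
#'
#' @param kind One of `"lsq"`, `"pearson"`, `"neyman1"`, `"neg_loglik"`,
#'   `"poisson_deviance"`.
#' @param counts Observed counts `m_i`.
#' @param expected Expected counts `mhat_i` (all kinds except `neg_loglik`).
#' @param probs Per-bin probabilities `p_i` (for `neg_loglik` only).
#' @return A single finite score, or `Inf` when a zero model value meets a
#'   positive count under `pearson` or `neg_loglik`.
#' @export
tcspc_score <- function(kind = score_kinds, counts, expected = NULL,
                        probs = NULL) {
  kind <- match.arg(kind)
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("invalid input: negative or non-finite counts", call. = FALSE)
  if (kind == "neg_loglik") {
    if (is.null(probs)) stop("neg_loglik requires `probs`", call. = FALSE)
    if (length(probs) != length(counts))
      stop("grid mismatch: counts and probs differ in length", call. = FALSE)
    if (any(probs <= 0 & counts > 0)) return(Inf)
    pos <- counts > 0
    return(-sum(counts[pos] * log(probs[pos])))
  }
  if (is.null(expected)) stop(sprintf("%s requires `expected`", kind), call. = FALSE)
  if (length(expected) != length(counts))
    stop("grid mismatch: counts and expected differ in length", call. = FALSE)
  m <- counts; mh <- expected
  switch(kind,
    lsq = sum((mh - m)^2),
    pearson = {
      if (any(mh <= 0 & m > 0)) return(Inf)
      if (any(mh <= 0)) mh[mh <= 0] <- .Machine$double.xmin
      sum((mh - m)^2 / mh)
    },
    neyman1 = {
      d <- ifelse(m == 0, 1, m)
      sum((mh - m)^2 / d)
    },
    poisson_deviance = {
      if (any(mh <= 0 & m > 0)) return(Inf)
      pos <- m > 0
      2 * (sum(m[pos] * log(m[pos] / mh[pos])) - sum(m) + sum(mh))
    }
  )
}

#' Reduced chi-square goodness of fit
#'
#' Score divided by the degrees of freedom `nu = K - 3` (three fitted
#' parameters: lifetime, background and amplitude). Values near one indicate
#' a well-specified model. For mean counts per bin below about one, the
#' expectation of the reduced Poisson deviance deviates from one while
#' Pearson's stays near one (at the price of a larger variance); grouping
#' adjacent bins via `rebin_factor` moves the deviance back toward one.
#'
#' @param hist A [tcspc_histogram()].
#' @param expected Expected counts on the same grid (from the fitted model).
#' @param kind `"pearson"` or `"poisson_deviance"`.
#' @param rebin_factor Optional integer factor for grouping adjacent bins
#'   before scoring.
#' @return The reduced chi-square (score / nu).
#' @export
reduced_chi2 <- function(hist, expected, kind = c("pearson", "poisson_deviance"),
                         rebin_factor = 1) {
  kind <- match.arg(kind)
  stopifnot(inherits(hist, "tcspc_histogram"))
  m <- rebin_values(hist$counts, rebin_factor)
  mh <- rebin_values(expected, rebin_factor)
  nu <- length(m) - 3
  if (nu <= 0) stop("degrees of freedom: need more than 3 bins", call. = FALSE)
  tcspc_score(kind, m, expected = mh) / nu
}
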