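#' Plot a fitted decay over the data
#'
#' Log-scale overlay of the (possibly windowed) histogram counts and the
#' fitted model expectation.
#'
#' @param fit A [fit_decay()] result.
#' @return A ggplot object.
#' @export
plot_decay_fit <- function(fit) {
  stopifnot(inherits(fit, "decay_fit"))
  df <- tibble::tibble(bin = seq_along(fit$counts),
                       counts = fit$counts, fitted = fit$expected)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$counts), size = 0.4,
                        alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), color = "#d1495b") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "TCSPC bin", y = "photons",
                  title = sprintf("tau = %.3g ns, b = %.3g (%s)",
                                  fit$tau_hat, fit$b_hat, fit$kind)) +
    ggplot2::theme_minimal()
}

#' Plot a photon-binned lifetime-variance curve
#'
#' Shows the per-group lifetime standard deviation, the CRLB at the group
#' means, and (when present) the combined prediction
#' `sqrt(crlb^2 + sigma_sample^2)` from [fit_intrinsic_variance()].
#'
#' @param object A [variance_curve()] (possibly with a `combined` column).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot variance_curve
#' @export
autoplot.variance_curve <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("mean_photons", "sigma", "crlb",
                                  intersect("combined", names(object)))],
    -"mean_photons", names_to = "quantity", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_photons, y = .data$value,
                                   color = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "mean photons per molecule",
                  y = "lifetime std. dev. (ns)") +
    ggplot2::theme_minimal()
}

#' Plot a classification ROC curve
#'
#' @param object A [classification_roc()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
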