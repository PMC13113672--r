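#' Plot the mean EPSC trajectory of a moment set
#'
#' Mean peak amplitude per stimulus with a +/- 1 SD ribbon, the standard
#' view of facilitation or depression across the train.
#'
#' @param object An [epsc_moments()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot epsc_moments
#' @export
autoplot.epsc_moments <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stimulus, y = .data$mean)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      alpha = 0.2
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = d$stimulus) +
    ggplot2::labs(x = "Stimulus index", y = "EPSC amplitude (pA)",
                  title = "Mean EPSC trajectory (+/- SD)")
}

#' Cross-stimulus covariance heatmap
#'
#' Visualizes the K x K covariance of EPSC amplitudes across sweeps; the
#' predominantly positive off-diagonal structure scaling with the product
#' of means is the signature of shared sweep-level quantal fluctuation.
#'
#' @param moments An [epsc_moments()] object.
#' @return A ggplot object.
#' @export
plot_covariance_heatmap <- function(moments) {
  k <- moments$n_stimuli
  d <- tidyr::expand_grid(i = seq_len(k), j = seq_len(k))
  d$covariance <- moments$cov[cbind(d$i, d$j)]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$j, y = .data$i, fill = .data$covariance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse(breaks = seq_len(k)) +
    ggplot2::scale_x_continuous(breaks = seq_len(k)) +
    ggplot2::labs(x = "Stimulus j", y = "Stimulus i",
                  fill = "Cov (pA²)",
                  title = "Cross-stimulus covariance")
}

#' Plot a moment-based quantal fit
#'
#' Left panel logic combined in one figure: the distribution of per-tuple
#' quantal-size candidates (kept candidates only) with the aggregated
#' estimate marked, and the recovered release probability sequence.
#'
#' @param object A `quantal_fit` from [quantal_estimate()].
#' @param ... Unused.
#' @return A ggplot object (candidate distribution); use
#'   [plot_release_sequence()] for the p trajectory.
#' @method autoplot quantal_fit
#' @export
autoplot.quantal_fit <- function(object, ...) {
  kept <- object$q_candidates$q
  kept <- kept[is.finite(kept) & kept > 0]
  ggplot2::ggplot(tibble::tibble(q = kept), ggplot2::aes(x = .data$q)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = object$q_hat, linetype = "dashed") +
    ggplot2::labs(x = "Quantal size candidate (pA)", y = "Count",
                  title = sprintf("q candidates across index tuples (q_hat = %.3g pA)",
                                  object$q_hat))
}

#' Release probability sequence plot
#'
#' @param fit A `quantal_fit` or `tm_fit`.
#' @return A ggplot object.
#' @export
plot_release_sequence <- function(fit) {
  d <- if (inherits(fit, "tm_fit")) {
    dplyr::rename(tidy(fit), p = "p_cal")
  } else {
    dplyr::rename(tidy(fit), p = "p_hat")
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stimulus, y = .data$p)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = d$stimulus) +
    ggplot2::labs(x = "Stimulus index", y = "Release probability",
                  title = "Estimated release probability sequence")
}

#' Plot a T-M calibration fit
#'
#' Observed vs fitted mean EPSC trajectory.
#'
#' @param object A `tm_fit` from [calibrate_tm()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tm_fit
#' @export
autoplot.tm_fit <- function(object, ...) {
  d <- tidyr::pivot_longer(tidy(object), c("mu_observed", "mu_fitted"),
                           names_to = "series", values_to = "mu")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stimulus, y = .data$mu,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Stimulus index", y = "Mean EPSC (pA)",
                  colour = NULL, title = "T-M calibration fit")
}

#' Plot a recovery report
#'
#' Bias and RMSE per parameter across the swept condition.
#'
#' @param object A `recovery_report` tibble.
#' @param metric `"rmse"` (default), `"bias"` or `"sd"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot recovery_report
#' @export
autoplot.recovery_report <- function(object, metric = c("rmse", "bias", "sd"), ...) {
  metric <- match.arg(metric)
  d <- dplyr::mutate(object, value = .data[[metric]])
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$condition), y = .data$value,
                                  colour = .data$estimator,
                                  group = .data$estimator)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = unique(d$condition_label)[1], y = toupper(metric),
                  title = sprintf("Parameter recovery: %s", toupper(metric)))
}
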