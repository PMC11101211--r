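#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a drift landscape and its energy profile
#'
#' @param object A [drift_landscape()].
#' @param ... Unused.
#' @return A ggplot: drift and energy versus position.
#' @export
autoplot.drift_landscape <- function(object, ...) {
  tidy.drift_landscape(object) |>
    tidyr::pivot_longer(c("drift_smooth", "energy"),
                        names_to = "profile", values_to = "value") |>
    dplyr::mutate(profile = dplyr::recode(.data$profile,
                                          drift_smooth = "drift G(x)",
                                          energy = "energy E(x)")) |>
    ggplot2::ggplot(ggplot2::aes(.data$position, .data$value)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~profile, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "position (line units)", y = NULL)
}

#' Plot a target-binned bias profile
#'
#' @param object A [compute_bias_profile()] result.
#' @param ... Unused.
#' @return A ggplot of bin bias versus target position.
#' @export
autoplot.bias_profile <- function(object, ...) {
  tidy.bias_profile(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$bin_center, .data$bias)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.6) +
    ggplot2::scale_size_area(max_size = 3) +
    ggplot2::labs(
      x = "target position (line units)", y = "mean error (line units)",
      title = sprintf("Bias profile at %g s delay", object$delay_s)
    )
}

#' Plot a bias saturation fit
#'
#' @param object A [fit_bias_curve()] result.
#' @param ... Unused.
#' @return A ggplot of bias versus delay with the fitted curve.
#' @export
autoplot.bias_fit <- function(object, ...) {
  grid <- seq(min(object$delays), max(object$delays), length.out = 100)
  curve <- tibble::tibble(delay_s = grid,
                          bias = predict(object, newdata = grid))
  tibble::tibble(delay_s = object$delays, bias = object$biases) |>
    ggplot2::ggplot(ggplot2::aes(.data$delay_s, .data$bias)) +
    ggplot2::geom_line(data = curve, colour = "firebrick") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "delay (s)", y = "overall bias (line units)")
}

#' Plot a proactive-interference curve
#'
#' @param object A [pi_spatial()] result.
#' @param ... Unused.
#' @return A ggplot of weighted mean error versus previous-response
#'   offset with the bootstrap ribbon.
#' @export
autoplot.pi_curve <- function(object, ...) {
  tidy.pi_curve(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$offset, .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted", colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "previous response - current target (line units)",
      y = "weighted mean error (line units)",
      title = sprintf("Proactive interference at %g s delay", object$delay_s)
    )
}

#' Plot attractor-comparison accuracy curves
#'
#' @param comparison Output of [attractor_comparison()].
#' @return A ggplot of MSE versus delay by condition.
#' @export
plot_attractor_comparison <- function(comparison) {
  comparison |>
    dplyr::mutate(condition = sprintf("%s, sigma=%g, beta_p=%g",
                                      .data$landscape, .data$sigma,
                                      .data$beta_p)) |>
    ggplot2::ggplot(ggplot2::aes(.data$delay_s, .data$mse,
                                 colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "delay (s)", y = "mean squared error",
                  colour = NULL)
}
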