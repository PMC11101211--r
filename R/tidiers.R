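#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a bias profile
#'
#' @param x A [compute_bias_profile()] result.
#' @param ... Unused.
#' @return One row per target bin: `bin_center`, `bias`, `n`.
#' @export
tidy.bias_profile <- function(x, ...) x$bins

#' @rdname tidy.bias_profile
#' @export
glance.bias_profile <- function(x, ...) {
  tibble::tibble(
    delay_s = x$delay_s, overall_bias = x$overall_bias,
    ci_lo = x$ci_lo, ci_hi = x$ci_hi, n = sum(x$bins$n)
  )
}

#' Tidy a bias saturation fit
#'
#' @param x A [fit_bias_curve()] result.
#' @param ... Unused.
#' @return One row per parameter with `term` and `estimate`; the rate
#'   row carries the bootstrap CI when available.
#' @export
tidy.bias_fit <- function(x, ...) {
  tibble::tibble(
    term = c("eta", "lambda", "b0"),
    estimate = c(x$eta, x$lambda, x$b0),
    ci_lo = c(NA, x$lambda_ci[1], NA),
    ci_hi = c(NA, x$lambda_ci[2], NA)
  )
}

#' @rdname tidy.bias_fit
#' @export
glance.bias_fit <- function(x, ...) {
  tibble::tibble(
    sse = x$sse, saturation_bias = x$eta + x$b0,
    converged = x$converged, identifiable = x$identifiable, form = x$form
  )
}

#' Tidy a mutual-information estimate
#'
#' @param x A [mutual_information()] result.
#' @param ... Unused.
#' @return Long tibble of the joint distribution with `target_bin`,
#'   `response_bin`, `prob`.
#' @export
tidy.mi_estimate <- function(x, ...) {
  n <- nrow(x$joint)
  tidyr::expand_grid(target_bin = seq_len(n), response_bin = seq_len(n)) |>
    dplyr::mutate(prob = as.numeric(t(x$joint)))
}

#' @rdname tidy.mi_estimate
#' @export
glance.mi_estimate <- function(x, ...) {
  tibble::tibble(
    mi_nats = x$mi_nats, ci_lo = x$ci_lo, ci_hi = x$ci_hi,
    n = x$n, n_bins = nrow(x$joint), ceiling_nats = log(nrow(x$joint))
  )
}

#' Tidy a proactive-interference curve
#'
#' @param x A [pi_spatial()] result.
#' @param ... Unused.
#' @return One row per offset: `offset`, `estimate`, `ci_lo`, `ci_hi`.
#' @export
tidy.pi_curve <- function(x, ...) x$curve

#' @rdname tidy.pi_curve
#' @export
glance.pi_curve <- function(x, ...) {
  tibble::tibble(
    delay_s = x$delay_s, range = x$range,
    range_ci_lo = x$range_ci[1], range_ci_hi = x$range_ci[2],
    range_se = x$range_se, n_trials = x$n_trials
  )
}

#' Tidy a fitted landscape model
#'
#' @param x A [fit_landscape_model()] result.
#' @param ... Unused.
#' @return One row per dynamics parameter (`term`, `estimate`).
#' @export
tidy.landscape_fit <- function(x, ...) {
  terms <- c("beta", "sigma", "t0",
             if (x$config$model == "plastic") c("beta_p", "sigma_p"))
  tibble::tibble(
    term = terms,
    estimate = vapply(terms, function(nm) x$params[[nm]], numeric(1))
  )
}

#' @rdname tidy.landscape_fit
#' @export
glance.landscape_fit <- function(x, ...) {
  tibble::tibble(
    model = x$config$model, cost = x$cost, k = x$k,
    n_evals = x$n_evals, converged = x$converged
  )
}

#' Tidy a drift landscape
#'
#' @param x A [drift_landscape()].
#' @param ... Unused.
#' @return One row per grid point: `position`, `drift`, `drift_smooth`,
#'   `energy` (from the smoothed drift).
#' @export
tidy.drift_landscape <- function(x, ...) {
  tibble::tibble(
    position = x$grid, drift = x$drift, drift_smooth = x$drift_smooth,
    energy = energy_from_drift(x)
  )
}

#' Tidy a model comparison
#'
#' @param x A [compare_models()] result.
#' @param ... Unused.
#' @return The per-model summary tibble.
#' @export
tidy.model_comparison <- function(x, ...) x$summary

#' @rdname tidy.model_comparison
#' @export
glance.model_comparison <- function(x, ...) {
  tibble::tibble(
    delta_aic = x$delta[["aic"]], delta_bic = x$delta[["bic"]],
    p_aic = x$p_aic, p_bic = x$p_bic, n = x$n, n_boot = x$n_boot
  )
}
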