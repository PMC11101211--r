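#' Remove inattentive trials
#'
#' Drops trials whose absolute error `|response - target|` exceeds the
#' attention threshold (default 0.25, roughly the 99% quantile of errors
#' in the behavioral data). Idempotent. Skipped trials are dropped as
#' well since they carry no response.
#'
#' @param trials A trial table (tibble with columns `participant`,
#'   `order`, `target`, `response`, `delay_s` and optionally `skipped`).
#' @param threshold Absolute-error cutoff in line units.
#' @return The filtered trial table with attribute `n_removed` (also
#'   printed in the message when trials are removed).
#' @export
attention_filter <- function(trials, threshold = 0.25) {
  skipped <- if ("skipped" %in% names(trials)) trials$skipped else FALSE
  err <- abs(trials$response - trials$target)
  drop <- skipped | (!is.na(err) & err > threshold)
  kept <- trials[!drop, , drop = FALSE]
  attr(kept, "n_removed") <- sum(drop)
  kept
}

#' Target-binned bias profile at one delay
#'
#' Bias at a position is the mean signed error (response minus target) of
#' trials whose target falls in that bin; the overall bias for the delay
#' is the maximum absolute bin bias over non-empty bins. Bins are
#' equal-width and non-overlapping, spanning the target range
#' `[0.1, 0.9]`. The overall bias is bootstrapped by resampling trials
#' with replacement.
#'
#' @param trials Trial table.
#' @param delay Delay (seconds) to select.
#' @param n_bins Number of target bins (default 41).
#' @param n_boot Bootstrap repetitions for the overall bias (default
#'   1000; 0 skips the bootstrap).
#' @param seed Bootstrap seed.
#' @param target_range Range spanned by the bins.
#' @return An object of class `bias_profile`: list with `bins` (tibble
#'   `bin_center`, `bias`, `n`), `overall_bias`, `boot` (bootstrap
#'   distribution of the overall bias), `ci_lo`, `ci_hi`, `delay_s`.
#' @export
compute_bias_profile <- function(trials, delay, n_bins = 41L, n_boot = 1000L,
                                 seed = 1L, target_range = c(0.1, 0.9)) {
  sub <- trials[trials$delay_s == delay & !is.na(trials$response), , drop = FALSE]
  if (nrow(sub) == 0L) stop("no trials at the requested delay", call. = FALSE)
  breaks <- seq(target_range[1], target_range[2], length.out = n_bins + 1L)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2

  profile_of <- function(df) {
    bin <- pmin(pmax(findInterval(df$target, breaks, rightmost.closed = TRUE), 1L), n_bins)
    err <- df$response - df$target
    bias <- vapply(seq_len(n_bins), function(b) {
      e <- err[bin == b]
      if (length(e)) mean(e) else NA_real_
    }, numeric(1))
    counts <- tabulate(bin, n_bins)
    list(bias = bias, counts = counts)
  }
  overall_of <- function(df) {
    p <- profile_of(df)
    max(abs(p$bias), na.rm = TRUE)
  }

  p <- profile_of(sub)
  overall <- max(abs(p$bias), na.rm = TRUE)
  boot <- NULL
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L) {
    bs <- bootstrap_statistic(sub, overall_of, n_reps = n_boot, seed = seed)
    boot <- bs$boot
    ci <- c(bs$ci_lo, bs$ci_hi)
  }
  structure(
    list(
      bins = tibble::tibble(bin_center = centers, bias = p$bias, n = p$counts),
      overall_bias = overall, boot = boot,
      ci_lo = ci[1], ci_hi = ci[2], delay_s = delay
    ),
    class = "bias_profile"
  )
}

#' @export
print.bias_profile <- function(x, ...) {
  cat(sprintf(
    "<bias_profile> delay %g s: overall bias %.4f (max |bin bias| over %d bins)\n",
    x$delay_s, x$overall_bias, nrow(x$bins)
  ))
  invisible(x)
}

#' Overall bias at every delay
#'
#' Convenience wrapper around [compute_bias_profile()] producing the
#' delay-vs-bias curve used by [fit_bias_curve()].
#'
#' @inheritParams compute_bias_profile
#' @param delays Delays to include (default: those present).
#' @return Tibble with `delay_s`, `bias`, `ci_lo`, `ci_hi`, `n`.
#' @export
bias_by_delay <- function(trials, delays = sort(unique(trials$delay_s)),
                          n_bins = 41L, n_boot = 1000L, seed = 1L) {
  purrr::map_dfr(delays, function(d) {
    bp <- compute_bias_profile(trials, d, n_bins = n_bins, n_boot = n_boot,
                               seed = derive_seed(seed, round(d * 10)))
    tibble::tibble(
      delay_s = d, bias = bp$overall_bias,
      ci_lo = bp$ci_lo, ci_hi = bp$ci_hi, n = sum(bp$bins$n)
    )
  })
}

bias_curve_value <- function(t, eta, lambda, b0, form) {
  if (form == "literal") eta * (1 + exp(-lambda * t)) + b0
  else eta * (1 - exp(-lambda * t)) + b0
}

#' Fit the bias saturation curve
#'
#' Fits the exponential saturation model
#' `B(t) = eta * (1 - exp(-lambda * t)) + B0` to overall bias versus
#' delay by least squares, using a derivative-free Nelder–Mead search on
#' a transformed parameterisation that keeps `lambda > 0`. `eta + B0` is
#' the bias at saturation, `lambda` the rate (1/s) and `B0` the bias at
#' zero delay. The printed form with `(1 + exp(-lambda t))` decays rather
#' than saturates; it is available via `form = "literal"` but the
#' saturating form is the default since it matches the interpretation of
#' `eta + B0` as the saturation bias.
#'
#' The time-constant uncertainty is estimated by a residual bootstrap:
#' residuals (inflated for the fitted parameters) are resampled with
#' replacement onto the fitted curve and the fit repeated. The reported
#' 95% interval for the rate is a log-scale interval using a Student-t
#' quantile with `n - 3` degrees of freedom on the bootstrap spread,
#' which keeps coverage near nominal with as few as six delays.
#'
#' @param delays Delay times (seconds), at least 3 distinct.
#' @param biases Overall bias at each delay.
#' @param form `"saturating"` (default) or `"literal"`.
#' @param n_boot Bootstrap repetitions for the rate (default 100).
#' @param seed Bootstrap seed.
#' @return Object of class `bias_fit`: list with `eta`, `lambda`, `b0`,
#'   `fitted`, `residuals`, `sse`, `lambda_boot`, `lambda_ci`,
#'   `converged`, `identifiable`, `form`.
#' @examples
#' d <- task_delays()
#' b <- 0.02 * (1 - exp(-0.5 * d)) + 0.005
#' fit_bias_curve(d, b, n_boot = 0)$lambda
#' @export
fit_bias_curve <- function(delays, biases, form = c("saturating", "literal"),
                           n_boot = 100L, seed = 1L) {
  form <- match.arg(form)
  if (length(delays) != length(biases)) {
    stop("`delays` and `biases` must have the same length", call. = FALSE)
  }
  if (length(unique(delays)) < 3L) {
    stop("need at least 3 distinct delays", call. = FALSE)
  }

  fit_once <- function(y) {
    # theta = (eta, log(lambda), b0)
    obj <- function(theta) {
      pred <- bias_curve_value(delays, theta[1], exp(theta[2]), theta[3], form)
      sum((pred - y)^2)
    }
    spread <- max(y) - min(y)
    init <- c(max(spread, 1e-4) * if (form == "literal") -1 else 1,
              log(1 / max(mean(delays), 1e-6)), y[which.min(delays)])
    best <- NULL
    for (lam0 in c(0.1, 0.5, 2)) {
      o <- stats::optim(c(init[1], log(lam0), init[3]), obj,
                        method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
      if (is.null(best) || o$value < best$value) best <- o
    }
    list(eta = best$par[1], lambda = exp(best$par[2]), b0 = best$par[3],
         sse = best$value, converged = best$convergence == 0)
  }

  f <- fit_once(biases)
  fitted <- bias_curve_value(delays, f$eta, f$lambda, f$b0, form)
  resid <- biases - fitted
  # lambda is unidentifiable when the curve is flat: eta ~ 0 means any rate
  # fits equally well
  identifiable <- abs(f$eta) > 10 * max(stats::sd(resid), 1e-12) / sqrt(length(delays))

  lambda_boot <- NULL
  lambda_ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L) {
    set.seed(seed)
    # residuals inflated by sqrt(n / (n - k)) so the resampled noise has
    # the right variance despite the 3 fitted parameters
    n_pts <- length(resid)
    r_scaled <- resid * sqrt(n_pts / max(n_pts - 3, 1))
    lambda_boot <- vapply(seq_len(n_boot), function(i) {
      y <- fitted + sample(r_scaled, n_pts, replace = TRUE)
      fit_once(y)$lambda
    }, numeric(1))
    # log-scale interval with a Student-t quantile at n - 3 degrees of
    # freedom: the rate is positive and right-skewed, and with only a
    # handful of delays the normal quantile undercovers badly
    tq <- stats::qt(0.975, max(n_pts - 3, 1))
    s_log <- stats::sd(log(pmax(lambda_boot, 1e-8)))
    lambda_ci <- exp(log(f$lambda) + c(-1, 1) * tq * s_log)
  }

  structure(
    list(
      eta = f$eta, lambda = f$lambda, b0 = f$b0,
      fitted = fitted, residuals = resid, sse = f$sse,
      delays = delays, biases = biases,
      lambda_boot = lambda_boot, lambda_ci = lambda_ci,
      converged = f$converged, identifiable = identifiable, form = form
    ),
    class = "bias_fit"
  )
}

#' @export
print.bias_fit <- function(x, ...) {
  cat(sprintf(
    "<bias_fit> %s form: eta %.4g, lambda %.4g /s, B0 %.4g (SSE %.3g)%s\n",
    x$form, x$eta, x$lambda, x$b0, x$sse,
    if (!x$identifiable) " [rate unidentifiable: flat curve]" else ""
  ))
  invisible(x)
}

#' Predict from a bias saturation fit
#'
#' @param object A [fit_bias_curve()] result.
#' @param newdata Optional delays at which to evaluate the curve.
#' @param ... Unused.
#' @return Predicted bias values.
#' @export
predict.bias_fit <- function(object, newdata = object$delays, ...) {
  bias_curve_value(newdata, object$eta, object$lambda, object$b0, object$form)
}
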