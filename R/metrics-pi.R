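# Attach the previous trial's response to each trial, within participant,
# by within-participant order. First trials drop out.
lag_trials <- function(trials) {
  trials |>
    dplyr::group_by(.data$participant) |>
    dplyr::arrange(.data$order, .by_group = TRUE) |>
    dplyr::mutate(prev_response = dplyr::lag(.data$response)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$prev_response), !is.na(.data$response))
}

#' Spatial proactive-interference curve
#'
#' Quantifies how the current response is pulled by the previous trial:
#' for each of 21 offsets `o` spanning `[-0.3, 0.3]`, the curve is the
#' Gaussian-kernel weighted mean of current-trial errors, with trial
#' weights `exp(-(offset_i - o)^2 / (2 * kernel_var))` where
#' `offset_i` is the previous trial's response minus the current trial's
#' target. An attractive (serial-dependence) effect produces a
#' derivative-of-Gaussian shape: positive mean error just above zero
#' offset, negative just below. The curve and its range
#' (max - min) are bootstrapped over trials.
#'
#' Current trials are first partitioned by target position into
#' `n_target_bins` bins; the offset curve is computed within each bin
#' (so the landscape's own target-dependent bias cannot masquerade as a
#' history effect) and the per-bin curves are averaged, weighted by bin
#' trial count. `target_bin` restricts the analysis to one target
#' interval instead.
#'
#' @param trials Trial table with `participant`, `order`, `target`,
#'   `response`, `delay_s`.
#' @param delay Delay (seconds) of the current trials to include.
#' @param offsets Offset grid (default 21 points from -0.3 to 0.3).
#' @param kernel_var Variance of the Gaussian weighting kernel
#'   (default 0.05, squared line units).
#' @param n_target_bins Number of current-target bins the curve is
#'   averaged over (default 50 equally spaced centers on `[0.1, 0.9]`,
#'   window width equal to the center spacing).
#' @param n_boot Bootstrap repetitions (default 100).
#' @param seed Bootstrap seed.
#' @param target_bin Optional `c(lo, hi)` interval restricting current
#'   trials by target position (replaces the bin average).
#' @return Object of class `pi_curve`: list with `curve` (tibble
#'   `offset`, `estimate`, `ci_lo`, `ci_hi`), `range` (max - min of the
#'   curve), `range_boot`, `range_ci`, `n_trials`, `delay_s`.
#' @export
pi_spatial <- function(trials, delay, offsets = seq(-0.3, 0.3, length.out = 21L),
                       kernel_var = 0.05, n_target_bins = 50L,
                       n_boot = 100L, seed = 1L, target_bin = NULL) {
  lagged <- lag_trials(trials)
  lagged <- lagged[lagged$delay_s == delay, , drop = FALSE]
  if (!is.null(target_bin)) {
    lagged <- lagged[lagged$target >= target_bin[1] &
                       lagged$target <= target_bin[2], , drop = FALSE]
  }
  if (nrow(lagged) < 2L) stop("not enough trials with a previous trial", call. = FALSE)

  off <- lagged$prev_response - lagged$target
  err <- lagged$response - lagged$target
  if (is.null(target_bin)) {
    centers <- seq(0.1, 0.9, length.out = n_target_bins)
    spacing <- centers[2] - centers[1]
    bin <- pmin(pmax(round((lagged$target - 0.1) / spacing) + 1L, 1L),
                n_target_bins)
  } else {
    bin <- rep(1L, nrow(lagged))
  }

  curve_of <- function(off, err, bin) {
    bins <- sort(unique(bin))
    num <- matrix(0, length(bins), length(offsets))
    den <- matrix(0, length(bins), length(offsets))
    for (k in seq_along(bins)) {
      sel <- bin == bins[k]
      w <- exp(-outer(off[sel], offsets, "-")^2 / (2 * kernel_var))
      num[k, ] <- colSums(w * err[sel])
      den[k, ] <- colSums(w)
    }
    n_b <- tabulate(match(bin, bins))
    per_bin <- num / den
    colSums(per_bin * n_b) / sum(n_b)
  }

  est <- curve_of(off, err, bin)
  n <- length(off)
  set.seed(seed)
  boot_curves <- matrix(NA_real_, nrow = n_boot, ncol = length(offsets))
  for (i in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    boot_curves[i, ] <- curve_of(off[idx], err[idx], bin[idx])
  }
  ci <- apply(boot_curves, 2, stats::quantile, probs = c(0.025, 0.975),
              na.rm = TRUE)
  range_boot <- apply(boot_curves, 1, function(v) max(v) - min(v))

  structure(
    list(
      curve = tibble::tibble(
        offset = offsets, estimate = est,
        ci_lo = ci[1, ], ci_hi = ci[2, ]
      ),
      range = max(est) - min(est),
      range_boot = range_boot,
      range_ci = stats::quantile(range_boot, c(0.025, 0.975), names = FALSE),
      range_se = stats::sd(range_boot),
      n_trials = n, delay_s = delay
    ),
    class = "pi_curve"
  )
}

#' @export
print.pi_curve <- function(x, ...) {
  cat(sprintf(
    "<pi_curve> delay %g s, %d trials: range %.4f [%.4f, %.4f]\n",
    x$delay_s, x$n_trials, x$range, x$range_ci[1], x$range_ci[2]
  ))
  invisible(x)
}

#' Temporal profile of proactive interference
#'
#' Range (max - min) of the spatial proactive-interference curve at each
#' delay, restricted to a reference target bin. By default the reference
#' bin is the target bin with maximal PI range at the longest delay.
#'
#' @inheritParams pi_spatial
#' @param delays Delays to evaluate (default: delays present).
#' @param reference_bin `c(lo, hi)` target interval, or `NULL` to select
#'   it automatically; `c(0.1, 0.9)` uses all targets.
#' @param n_reference_bins Candidate bins scanned when selecting the
#'   reference automatically.
#' @return Tibble with `delay_s`, `range`, `ci_lo`, `ci_hi`, `se`,
#'   `n_trials`; the reference bin is attached as an attribute.
#' @export
pi_temporal <- function(trials, delays = sort(unique(trials$delay_s)),
                        reference_bin = NULL, n_reference_bins = 8L,
                        offsets = seq(-0.3, 0.3, length.out = 21L),
                        kernel_var = 0.05, n_boot = 100L, seed = 1L) {
  if (is.null(reference_bin)) {
    edges <- seq(0.1, 0.9, length.out = n_reference_bins + 1L)
    longest <- max(delays)
    ranges <- vapply(seq_len(n_reference_bins), function(b) {
      bin <- c(edges[b], edges[b + 1])
      r <- try(pi_spatial(trials, longest, offsets, kernel_var,
                          n_boot = 2L, seed = seed, target_bin = bin),
               silent = TRUE)
      if (inherits(r, "try-error")) NA_real_ else r$range
    }, numeric(1))
    if (all(is.na(ranges))) stop("no reference bin has enough trials", call. = FALSE)
    b <- which.max(ranges)
    reference_bin <- c(edges[b], edges[b + 1])
  }
  out <- purrr::map_dfr(delays, function(d) {
    r <- try(pi_spatial(trials, d, offsets, kernel_var, n_boot = n_boot,
                        seed = derive_seed(seed, round(d * 10)),
                        target_bin = reference_bin),
             silent = TRUE)
    if (inherits(r, "try-error")) {
      warning(sprintf("delay %g s omitted: too few trials in the reference bin", d))
      return(tibble::tibble())
    }
    tibble::tibble(
      delay_s = d, range = r$range,
      ci_lo = r$range_ci[1], ci_hi = r$range_ci[2],
      se = r$range_se, n_trials = r$n_trials
    )
  })
  attr(out, "reference_bin") <- reference_bin
  out
}
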