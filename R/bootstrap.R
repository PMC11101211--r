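#' Bootstrap a statistic of a trial table
#'
#' Nonparametric bootstrap by resampling rows with replacement. Confidence
#' intervals are percentile intervals and p-values are empirical: the
#' fraction of resamples on the far side of `null_value`, two-sided by
#' doubling the smaller tail, floored at `1 / n_reps` (when no resample
#' crosses the null the p-value is reported as below the floor).
#'
#' @param data A data frame (rows are the resampling unit) or a vector.
#' @param statistic Function of a resampled `data` returning one number.
#' @param n_reps Number of bootstrap resamples (>= 2).
#' @param seed Seed for the resampling.
#' @param null_value Null value for the empirical p-value. Default 0.
#' @param conf Confidence level for the percentile interval.
#' @return A list with `estimate` (statistic of the original data),
#'   `boot` (vector of resample statistics), `ci_lo`, `ci_hi`, `se`,
#'   `p_value`, `p_floor` (`TRUE` when no resample crossed the null, so
#'   the p-value is an upper bound) and `p_label` (e.g. `"<0.001"`).
#' @examples
#' bootstrap_statistic(rnorm(100), mean, n_reps = 200, seed = 1)$ci_lo
#' @export
bootstrap_statistic <- function(data, statistic, n_reps = 1000L, seed = 1L,
                                null_value = 0, conf = 0.95) {
  if (n_reps < 2L) stop("`n_reps` must be at least 2", call. = FALSE)
  is_df <- is.data.frame(data)
  n <- if (is_df) nrow(data) else length(data)
  if (n < 1L) stop("`data` is empty", call. = FALSE)
  est <- statistic(data)
  set.seed(seed)
  boot <- vapply(seq_len(n_reps), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    statistic(if (is_df) data[idx, , drop = FALSE] else data[idx])
  }, numeric(1))
  alpha <- (1 - conf) / 2
  qs <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE, na.rm = TRUE)
  lower_tail <- mean(boot <= null_value)
  upper_tail <- mean(boot >= null_value)
  p <- min(1, 2 * min(lower_tail, upper_tail))
  floor_hit <- p < 1 / n_reps
  p <- max(p, 1 / n_reps)
  list(
    estimate = est, boot = boot,
    ci_lo = qs[1], ci_hi = qs[2], se = stats::sd(boot),
    p_value = p, p_floor = floor_hit,
    p_label = if (floor_hit) sprintf("<%g", 1 / n_reps) else sprintf("%g", p)
  )
}
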