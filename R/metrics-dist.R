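#' Response-distribution set
#'
#' The common object data and model are reduced to for fitting: for every
#' (target bin, delay) cell, a probability vector over error bins
#' (`response - target`) spanning `[-0.25, 0.25]`. Stored as a 3-d array
#' `prob[error_bin, target_bin, delay]` with the bin centers and delays
#' as attributes; every cell vector sums to 1.
#'
#' @param prob 3-d array `error_bin x target_bin x delay`.
#' @param error_centers,target_centers Bin-center positions.
#' @param delays Task delays (seconds) along the third dimension.
#' @return An object of class `response_distribution_set`.
#' @export
response_distribution_set <- function(prob, error_centers, target_centers, delays) {
  stopifnot(length(dim(prob)) == 3L,
            dim(prob)[1] == length(error_centers),
            dim(prob)[2] == length(target_centers),
            dim(prob)[3] == length(delays))
  structure(prob,
            error_centers = error_centers,
            target_centers = target_centers,
            delays = delays,
            class = "response_distribution_set")
}

#' @export
print.response_distribution_set <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<response_distribution_set> %d error bins x %d target bins x %d delays\n",
    d[1], d[2], d[3]
  ))
  invisible(x)
}

#' @export
as_tibble.response_distribution_set <- function(x, ...) {
  d <- dim(x)
  tidyr::expand_grid(
    delay_s = attr(x, "delays"),
    target = attr(x, "target_centers"),
    error = attr(x, "error_centers")
  ) |>
    dplyr::arrange(.data$delay_s, .data$target, .data$error) |>
    dplyr::mutate(prob = as.numeric(aperm(unclass(x), c(1, 2, 3))))
}

# Length-3 moving-mean filter with edge bins averaging their available
# neighbors; output renormalized to sum 1.
stencil3 <- function(p) {
  n <- length(p)
  out <- p
  if (n >= 3L) {
    out[2:(n - 1)] <- (p[1:(n - 2)] + p[2:(n - 1)] + p[3:n]) / 3
    out[1] <- (p[1] + p[2]) / 2
    out[n] <- (p[n - 1] + p[n]) / 2
  }
  out / sum(out)
}

# Gaussian KDE of errors evaluated at fixed bin centers, returned as a
# probability vector. Degenerate inputs (no spread, or a single point)
# become a point mass at the nearest bin; empty input becomes uniform.
kde_error_vector <- function(errors, centers, bw = NULL) {
  n_bins <- length(centers)
  if (length(errors) == 0L) return(rep(1 / n_bins, n_bins))
  lo <- centers[1]
  hi <- centers[n_bins]
  w <- centers[2] - centers[1]
  errors <- pmin(pmax(errors, lo - w / 2), hi + w / 2)
  if (length(errors) < 2L || stats::sd(errors) < 1e-12) {
    p <- numeric(n_bins)
    p[which.min(abs(centers - mean(errors)))] <- 1
    return(p)
  }
  bw <- bw %||% stats::bw.nrd0(errors)
  dens <- stats::density(errors, bw = bw, from = lo, to = hi, n = n_bins)
  p <- dens$y
  if (sum(p) <= 0) return(rep(1 / n_bins, n_bins))
  p / sum(p)
}

#' Estimate response-error distributions per target bin and delay
#'
#' Reduces a trial table (observed or simulated) to a
#' [response_distribution_set()]: trials are binned by target value into
#' `n_target_bins` equally spaced bin centers on `[0.1, 0.9]` (nearest
#' center), and within each (target bin, delay) cell the distribution of
#' errors is estimated by Gaussian kernel density (normal-reference
#' bandwidth by default) evaluated on `n_error_bins` bins spanning
#' `[-0.25, 0.25]` and normalized to sum 1. Model-side distributions are
#' additionally smoothed with a length-3 moving mean
#' (`smooth_stencil = TRUE`) to reduce Monte-Carlo jitter before
#' comparison. Empty cells become uniform vectors and are reported in the
#' `empty_cells` attribute.
#'
#' @param trials Trial table with `target`, `response`, `delay_s`.
#' @param delays Delays to include (default: the task set).
#' @param n_target_bins,n_error_bins Bin counts (default 50 each).
#' @param error_range Error support (default `c(-0.25, 0.25)`); errors
#'   outside are clipped to the edge.
#' @param target_range Range of the target bin centers.
#' @param smooth_stencil Apply the length-3 moving mean (model side).
#' @param bw Optional fixed KDE bandwidth (line units).
#' @return A [response_distribution_set()].
#' @export
estimate_response_distributions <- function(trials, delays = task_delays(),
                                            n_target_bins = 50L,
                                            n_error_bins = 50L,
                                            error_range = c(-0.25, 0.25),
                                            target_range = c(0.1, 0.9),
                                            smooth_stencil = FALSE, bw = NULL) {
  w <- diff(error_range) / n_error_bins
  error_centers <- seq(error_range[1] + w / 2, error_range[2] - w / 2,
                       length.out = n_error_bins)
  target_centers <- seq(target_range[1], target_range[2],
                        length.out = n_target_bins)
  spacing <- if (n_target_bins > 1L) target_centers[2] - target_centers[1] else 1

  prob <- array(0, dim = c(n_error_bins, n_target_bins, length(delays)))
  empty <- 0L
  for (di in seq_along(delays)) {
    sub <- trials[trials$delay_s == delays[di] & !is.na(trials$response), , drop = FALSE]
    bin <- pmin(pmax(round((sub$target - target_range[1]) / spacing) + 1L, 1L),
                n_target_bins)
    err <- sub$response - sub$target
    for (bi in seq_len(n_target_bins)) {
      e <- err[bin == bi]
      if (length(e) == 0L) empty <- empty + 1L
      p <- kde_error_vector(e, error_centers, bw = bw)
      if (smooth_stencil) p <- stencil3(p)
      prob[, bi, di] <- p
    }
  }
  out <- response_distribution_set(prob, error_centers, target_centers, delays)
  attr(out, "empty_cells") <- empty
  if (empty > 0L) {
    message(sprintf("%d empty (target bin, delay) cells set to uniform", empty))
  }
  out
}
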