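#' Binned mutual information between target and response
#'
#' Plug-in estimator of the mutual information (in nats) between target
#' and response positions, using `n_bins` equal-width bins spanning the
#' full line `[0, 1]` for both marginals and the joint. Cells where
#' `P(T) * P(R) = 0` contribute 0. For a discrete attractor with `n`
#' wells, the steady-state MI is bounded by `ln(n)`; the estimator itself
#' is bounded by `ln(n_bins)`.
#'
#' @param targets,responses Paired position vectors in `[0, 1]` (values
#'   outside are clipped).
#' @param n_bins Number of bins (default 12).
#' @param n_boot Bootstrap repetitions for the MI variance (default 100;
#'   0 skips).
#' @param seed Bootstrap seed.
#' @return Object of class `mi_estimate`: list with `mi_nats`, `joint`
#'   (n_bins x n_bins probability matrix), `p_target`, `p_response`,
#'   `boot`, `ci_lo`, `ci_hi`, `n`.
#' @examples
#' x <- runif(1000)
#' mutual_information(x, x, n_boot = 0)$mi_nats  # near ln(12)
#' @export
mutual_information <- function(targets, responses, n_bins = 12L,
                               n_boot = 100L, seed = 1L) {
  if (length(targets) != length(responses)) {
    stop("`targets` and `responses` must be paired", call. = FALSE)
  }
  if (length(targets) < 1L) stop("need at least one pair", call. = FALSE)
  keep <- is.finite(targets) & is.finite(responses)
  targets <- pmin(pmax(targets[keep], 0), 1)
  responses <- pmin(pmax(responses[keep], 0), 1)

  bin_of <- function(x) pmin(floor(x * n_bins) + 1L, n_bins)
  mi_of <- function(tb, rb) {
    joint <- matrix(0, n_bins, n_bins)
    tab <- table(factor(tb, levels = seq_len(n_bins)),
                 factor(rb, levels = seq_len(n_bins)))
    joint[] <- tab / sum(tab)
    pt <- rowSums(joint)
    pr <- colSums(joint)
    denom <- outer(pt, pr)
    ok <- joint > 0 & denom > 0
    mi <- sum(joint[ok] * log(joint[ok] / denom[ok]))
    list(mi = max(mi, 0), joint = joint, pt = pt, pr = pr)
  }

  tb <- bin_of(targets)
  rb <- bin_of(responses)
  m <- mi_of(tb, rb)

  boot <- NULL
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L) {
    n <- length(tb)
    set.seed(seed)
    boot <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      mi_of(tb[idx], rb[idx])$mi
    }, numeric(1))
    ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
  }

  structure(
    list(
      mi_nats = m$mi, joint = m$joint,
      p_target = m$pt, p_response = m$pr,
      boot = boot, ci_lo = ci[1], ci_hi = ci[2], n = length(tb)
    ),
    class = "mi_estimate"
  )
}

#' @export
print.mi_estimate <- function(x, ...) {
  cat(sprintf(
    "<mi_estimate> %.4f nats (%d bins, n = %d; ceiling ln(%d) = %.3f)\n",
    x$mi_nats, nrow(x$joint), x$n, nrow(x$joint), log(nrow(x$joint))
  ))
  invisible(x)
}

#' 1-D earth mover's distance between probability vectors
#'
#' For distributions on a common equispaced 1-D support, the optimal
#' transport cost equals the L1 distance between the cumulative
#' distribution functions times the bin width.
#'
#' @param p,q Probability vectors of equal length, each summing to 1.
#' @param bin_width Spacing of the support (line units). Default `1 /
#'   length(p)` so the support spans one line unit.
#' @return Non-negative distance in line units.
#' @export
emd_1d <- function(p, q, bin_width = 1 / length(p)) {
  if (length(p) != length(q)) stop("`p` and `q` must have equal length", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-8 || abs(sum(q) - 1) > 1e-8 || any(p < 0) || any(q < 0)) {
    stop("`p` and `q` must be probability vectors summing to 1", call. = FALSE)
  }
  sum(abs(cumsum(p) - cumsum(q))) * bin_width
}

#' Coefficient of determination over vectorized distribution sets
#'
#' Concatenates all cells of model and data response-distribution sets
#' and computes `1 - SS_res / SS_tot`, where `SS_tot` is taken about the
#' grand mean of the data vector. A model no better than the grand mean
#' scores 0; worse models go negative.
#'
#' @param model,data [response_distribution_set()] objects or numeric
#'   arrays of matching shape.
#' @return A single number (at most 1).
#' @export
r2_vectorized <- function(model, data) {
  m <- as.numeric(unclass(model))
  d <- as.numeric(unclass(data))
  if (length(m) != length(d)) stop("shapes do not match", call. = FALSE)
  ss_res <- sum((d - m)^2)
  ss_tot <- sum((d - mean(d))^2)
  1 - ss_res / ss_tot
}
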