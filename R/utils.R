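#' Delay set of the delayed-estimation task
#'
#' The six retention delays (seconds) used in the task design.
#'
#' @return Numeric vector of delays in seconds.
#' @export
task_delays <- function() c(0, 1, 3, 6, 13, 20)

# Derive a reproducible 32-bit sub-seed from a root seed and up to two
# stream indices. Injective for i <= 131070 and j < 131071, which covers
# every (start, run) and (participant, trial) stream the package creates.
derive_seed <- function(seed, i = 0L, j = 0L) {
  s <- (as.numeric(seed) %% 1e6) * 1009 + as.numeric(i) * 131071 + as.numeric(j)
  as.integer(s %% 2147483647) + 1L
}

# Reflect positions into [0, 1]; exact identity on the interior, exact
# for excursions within (-1, 2), which per-step displacements cannot
# exceed under the parameter bounds.
reflect01 <- function(x) {
  out <- x < 0 | x > 1
  if (any(out)) {
    y <- abs(x[out])
    x[out] <- 1 - abs(1 - y)
  }
  x
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
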