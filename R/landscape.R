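#' Drift landscape on a gridded line
#'
#' A drift landscape holds the drift profile `G(x)` — the negative gradient
#' of the energy landscape `E(x)` — sampled at equidistant grid points on
#' `[0, 1]` (normalized line units). The memory trace drifts with velocity
#' `beta * G(x)` and diffuses under additive Gaussian noise. Before use, the
#' raw drift values are smoothed with a Gaussian kernel so the fitted model
#' does not depend too strongly on any single grid value; the smoothing
#' width is expressed in line units and the operator preserves constant
#' profiles exactly (edge-renormalized weights).
#'
#' @param drift Numeric vector of drift values, one per grid point
#'   (line units per second).
#' @param n_grid Number of grid points if `drift` is a single value to be
#'   recycled; ignored otherwise. Default 50.
#' @param smoothing_width Standard deviation of the Gaussian smoothing
#'   kernel in line units. `0` disables smoothing. Default `0.02`
#'   (about one grid spacing at 50 points).
#'
#' @return An object of class `drift_landscape` with fields `grid`,
#'   `drift` (raw values), `drift_smooth` (values used by the dynamics)
#'   and `smoothing_width`.
#' @examples
#' flat <- drift_landscape(0)
#' restoring <- drift_landscape(0.5 - seq(0, 1, length.out = 50))
#' @export
drift_landscape <- function(drift, n_grid = 50L, smoothing_width = 0.02) {
  if (length(drift) == 1L) drift <- rep(drift, n_grid)
  n <- length(drift)
  if (n < 3L) stop("a drift landscape needs at least 3 grid points", call. = FALSE)
  if (!all(is.finite(drift))) stop("drift values must be finite", call. = FALSE)
  stopifnot_scalar(smoothing_width, "smoothing_width")
  if (smoothing_width < 0) stop("`smoothing_width` must be non-negative", call. = FALSE)
  grid <- seq(0, 1, length.out = n)
  structure(
    list(
      grid = grid,
      drift = as.numeric(drift),
      drift_smooth = smooth_drift(as.numeric(drift), grid, smoothing_width),
      smoothing_width = smoothing_width
    ),
    class = "drift_landscape"
  )
}

#' @export
print.drift_landscape <- function(x, ...) {
  cat(sprintf(
    "<drift_landscape> %d grid points on [0,1], smoothing width %g\n",
    length(x$grid), x$smoothing_width
  ))
  cat(sprintf(
    "  drift range [%.4g, %.4g]\n",
    min(x$drift), max(x$drift)
  ))
  invisible(x)
}

# Gaussian smoothing of a gridded profile. Weights are renormalized per
# output point, so a constant profile is reproduced exactly and no mass
# leaks at the boundaries.
smooth_drift <- function(values, grid, width) {
  if (width == 0) return(values)
  w <- exp(-outer(grid, grid, "-")^2 / (2 * width^2))
  w <- w / rowSums(w)
  as.numeric(w %*% values)
}

#' Interpolate drift at arbitrary positions
#'
#' Linear interpolation of the (smoothed) drift profile. Exact at grid
#' points.
#'
#' @param landscape A [drift_landscape()].
#' @param x Positions in `[0, 1]`.
#' @return Drift values at `x` (line units per second).
#' @export
drift_at <- function(landscape, x) {
  if (any(x < 0 | x > 1)) stop("positions must lie in [0, 1]", call. = FALSE)
  d <- landscape$drift_smooth
  n <- length(d)
  h <- 1 / (n - 1)
  idx <- pmin(floor(x / h), n - 2)
  frac <- x / h - idx
  d[idx + 1] * (1 - frac) + d[idx + 2] * frac
}

#' Energy profile from a drift profile
#'
#' The energy is the negative antiderivative of the drift,
#' `G(x) = -dE/dx`, computed by cumulative trapezoidal integration and
#' anchored so that `min(E) = 0`.
#'
#' @param landscape A [drift_landscape()].
#' @param smoothed Use the smoothed drift (default) or the raw values.
#' @return Numeric vector of energies, one per grid point.
#' @export
energy_from_drift <- function(landscape, smoothed = TRUE) {
  d <- if (smoothed) landscape$drift_smooth else landscape$drift
  g <- landscape$grid
  h <- diff(g)
  e <- -c(0, cumsum((d[-length(d)] + d[-1]) / 2 * h))
  e - min(e)
}

#' Drift profile from an energy profile
#'
#' Inverts [energy_from_drift()]. The trapezoidal integral determines the
#' drift up to its value at the first grid point; when `drift0` is
#' supplied the inversion is exact (a two-term recurrence), otherwise a
#' central-difference gradient is used as an approximation.
#'
#' @param energy Numeric energy values per grid point.
#' @param grid Grid positions (default 50 equidistant points on `[0,1]`).
#' @param drift0 Optional drift value at the first grid point for exact
#'   inversion.
#' @return Numeric drift values.
#' @export
drift_from_energy <- function(energy, grid = seq(0, 1, length.out = length(energy)),
                              drift0 = NULL) {
  n <- length(energy)
  h <- diff(grid)
  if (!is.null(drift0)) {
    d <- numeric(n)
    d[1] <- drift0
    for (i in seq_len(n - 1)) {
      d[i + 1] <- -2 * (energy[i + 1] - energy[i]) / h[i] - d[i]
    }
    return(d)
  }
  d <- numeric(n)
  d[1] <- -(energy[2] - energy[1]) / h[1]
  d[n] <- -(energy[n] - energy[n - 1]) / h[n - 1]
  d[2:(n - 1)] <- -(energy[3:n] - energy[1:(n - 2)]) / (grid[3:n] - grid[1:(n - 2)])
  d
}

#' Idealized two-well landscape
#'
#' Builds the discrete-attractor drift profile used in the simulation and
#' parameter-recovery studies: a smooth cubic with stable zero crossings
#' (negative slope) exactly at the two well centers and one unstable
#' crossing at the barrier between them,
#' `G(x) = -a (x - c1)(x - b)(x - c2)`.
#'
#' The default depth scale puts the drift within the fitting bounds
#' (|G| < 5 on `[0, 1]`) and gives a well relaxation time of a few seconds
#' at drift strengths in the fitted range, so biases saturate within the
#' 20 s task horizon.
#'
#' @param centers Two well positions inside `(0, 1)`.
#' @param depth_scale Overall drift amplitude `a` (larger = deeper wells).
#' @param barrier Position of the unstable fixed point between the wells.
#' @param n_grid,smoothing_width Passed to [drift_landscape()]. Smoothing
#'   defaults to 0 so the fixed points stay exactly at the stated
#'   positions.
#' @return A [drift_landscape()].
#' @examples
#' tw <- two_well_landscape()
#' drift_at(tw, 0.3)  # 0: stable fixed point
#' @export
two_well_landscape <- function(centers = c(0.3, 0.7), depth_scale = 40,
                               barrier = mean(centers), n_grid = 50L,
                               smoothing_width = 0) {
  centers <- sort(centers)
  if (length(centers) != 2L || any(centers <= 0) || any(centers >= 1) ||
      diff(centers) < 1e-6) {
    stop("`centers` must be two distinct positions inside (0, 1)", call. = FALSE)
  }
  if (barrier <= centers[1] || barrier >= centers[2]) {
    stop("`barrier` must lie strictly between the well centers", call. = FALSE)
  }
  if (depth_scale <= 0) stop("`depth_scale` must be positive", call. = FALSE)
  grid <- seq(0, 1, length.out = n_grid)
  d <- -depth_scale * (grid - centers[1]) * (grid - barrier) * (grid - centers[2])
  drift_landscape(d, smoothing_width = smoothing_width)
}

#' Read / write a landscape as two-column text
#'
#' Plain-text serialization: comment header lines carry the smoothing
#' width, followed by whitespace-separated `position drift` rows at full
#' double precision (round-trips to 15 significant digits).
#'
#' @param landscape A [drift_landscape()].
#' @param path File path.
#' @return `write_landscape()` returns `path` invisibly;
#'   `read_landscape()` returns a [drift_landscape()].
#' @export
write_landscape <- function(landscape, path) {
  lines <- c(
    sprintf("# smoothing_width %.17g", landscape$smoothing_width),
    sprintf("%.17g %.17g", landscape$grid, landscape$drift)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  width <- 0
  m <- grep("smoothing_width", meta, value = TRUE)
  if (length(m)) width <- as.numeric(sub(".*smoothing_width\\s+", "", m[1]))
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- do.call(rbind, strsplit(trimws(body), "\\s+"))
  drift_landscape(as.numeric(parts[, 2]), smoothing_width = width)
}
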