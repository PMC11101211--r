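# Shared fixtures and independent oracles, all built in code.

# Minimal trial table with exact responses (errors injectable).
make_trials <- function(targets, responses = targets,
                        delays = rep(1, length(targets)),
                        participant = "P1") {
  tibble::tibble(
    participant = participant,
    order = seq_along(targets),
    target = targets,
    response = responses,
    delay_s = delays,
    skipped = FALSE
  )
}

# Independent 1-D earth mover's oracle: greedy mass transport between
# histogram bins (never uses the CDF identity the implementation relies on).
emd_greedy <- function(p, q, bin_width) {
  supply <- p
  demand <- q
  cost <- 0
  i <- 1L
  j <- 1L
  n <- length(p)
  while (i <= n && j <= n) {
    m <- min(supply[i], demand[j])
    cost <- cost + m * abs(i - j) * bin_width
    supply[i] <- supply[i] - m
    demand[j] <- demand[j] - m
    if (supply[i] <= 1e-15) i <- i + 1L
    if (demand[j] <= 1e-15) j <- j + 1L
  }
  cost
}

# Independent deterministic trajectory oracle: fine-step Euler descent on
# the interpolated drift, using stats::approx rather than the package's
# interpolation.
ode_descend <- function(landscape, beta, x0, t_end, dt = 0.002) {
  x <- x0
  for (k in seq_len(round(t_end / dt))) {
    g <- stats::approx(landscape$grid, landscape$drift_smooth, xout = x,
                       rule = 2)$y
    x <- x + beta * g * dt
    x <- min(max(x, 0), 1)
  }
  x
}

# Random probability vector.
rprob <- function(n) {
  v <- stats::rexp(n)
  v / sum(v)
}
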