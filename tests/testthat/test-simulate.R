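test_that("plasticity kernel is an odd attractive bump derivative", {
  grid <- seq(0, 1, length.out = 201)
  k <- plastic_kernel(0.5, grid, sigma_p = 0.05)
  expect_equal(k[grid == 0.5], 0)
  # odd about the center: sums to zero on a symmetric grid
  expect_lt(abs(sum(k)), 1e-12)
  # attractive: positive drift below the center, negative above
  expect_true(all(k[grid > 0.4 & grid < 0.5] > 0))
  expect_true(all(k[grid > 0.5 & grid < 0.6] < 0))
  # calculus oracle: |extrema| at x0 +/- sigma_p with value sigma_p e^{-1/2}
  fine <- seq(0, 1, length.out = 20001)
  kf <- plastic_kernel(0.5, fine, sigma_p = 0.05)
  expect_equal(fine[which.max(kf)], 0.5 - 0.05, tolerance = 1e-3)
  expect_equal(max(kf), 0.05 * exp(-0.5), tolerance = 1e-6)
  expect_error(plastic_kernel(0.5, fine, sigma_p = 0), "positive")
})

test_that("noise-free, drift-free trajectories stay put", {
  flat <- drift_landscape(0)
  p <- dynamics_params(beta = 0, sigma = 0, t0 = 0)
  pos <- simulate_landscape(flat, p, c(0.2, 0.5, 0.8), c(0, 5, 20),
                            n_runs = 3, seed = 1)
  for (ti in 1:3) expect_equal(pos[, , ti], pos[, , 1])
  expect_equal(pos[, 1, 1], c(0.2, 0.5, 0.8))
})

test_that("pure diffusion follows the literal-discretization variance law", {
  flat <- drift_landscape(0)
  p <- dynamics_params(beta = 0, sigma = 0.1, t0 = 0)
  n <- 10000L
  t_end <- 10
  pos <- simulate_landscape(flat, p, 0.5, t_end, n_runs = n, seed = 2)
  v <- stats::var(as.numeric(pos))
  theory <- p$sigma^2 * t_end * p$dt
  se <- theory * sqrt(2 / (n - 1))
  expect_lt(abs(v - theory), 3 * se)
})

test_that("sqrt-dt scaling gives the standard Brownian variance", {
  flat <- drift_landscape(0)
  p <- dynamics_params(beta = 0, sigma = 0.03, t0 = 0,
                       noise_scaling = "sqrt_dt")
  pos <- simulate_landscape(flat, p, 0.5, 5, n_runs = 10000L, seed = 3)
  theory <- p$sigma^2 * 5
  expect_lt(abs(stats::var(as.numeric(pos)) - theory),
            3 * theory * sqrt(2 / 9999))
})

test_that("plastic simulator with zero plasticity reproduces the static one exactly", {
  tw <- two_well_landscape()
  p <- params_plastic_fit(beta_p = 0)
  times <- p$t0 + c(0, 1, 6, 20)
  a <- simulate_landscape(tw, p, c(0.2, 0.45, 0.8), times, n_runs = 20,
                          seed = 7, engine = "static")
  b <- simulate_landscape(tw, p, c(0.2, 0.45, 0.8), times, n_runs = 20,
                          seed = 7, engine = "plastic")
  expect_identical(a, b)
})

test_that("simulations are seed-deterministic and seed-sensitive", {
  tw <- two_well_landscape()
  p <- params_static_fit()
  a <- simulate_landscape(tw, p, 0.4, p$t0 + 6, n_runs = 2000, seed = 10)
  b <- simulate_landscape(tw, p, 0.4, p$t0 + 6, n_runs = 2000, seed = 10)
  expect_identical(a, b)
  c <- simulate_landscape(tw, p, 0.4, p$t0 + 6, n_runs = 2000, seed = 11)
  expect_false(identical(a, c))
  # same-distribution check across seeds
  ks <- suppressWarnings(stats::ks.test(as.numeric(a), as.numeric(c)))
  expect_gt(ks$p.value, 0.01)
})

test_that("adding runs does not perturb existing noise substreams", {
  tw <- two_well_landscape()
  p <- params_static_fit()
  small <- simulate_landscape(tw, p, c(0.3, 0.6), p$t0 + 3, n_runs = 5, seed = 4)
  big <- simulate_landscape(tw, p, c(0.3, 0.6), p$t0 + 3, n_runs = 9, seed = 4)
  expect_identical(small[, 1:5, ], big[, 1:5, ])
})

test_that("noiseless descent converges to the basin minimum", {
  tw <- two_well_landscape()
  p <- dynamics_params(beta = 0.15, sigma = 0, t0 = 0)
  starts <- c(0.12, 0.25, 0.42, 0.58, 0.77, 0.88)
  pos <- simulate_landscape(tw, p, starts, 60, seed = 1)
  finals <- pos[, 1, 1]
  oracle <- vapply(starts, function(s) ode_descend(tw, p$beta, s, 60),
                   numeric(1))
  expect_equal(finals, oracle, tolerance = 1 / 49)
  expect_true(all(abs(finals[starts < 0.5] - 0.3) < 1 / 49))
  expect_true(all(abs(finals[starts > 0.5] - 0.7) < 1 / 49))
})

test_that("plasticity impedes descent into the well", {
  tw <- two_well_landscape()
  times <- seq(0, 40, by = 0.5)
  tol <- 1 / 49
  time_to_reach <- function(beta_p) {
    p <- dynamics_params(beta = 0.08, sigma = 0, t0 = 0,
                         beta_p = beta_p, sigma_p = 0.0218)
    pos <- simulate_landscape(tw, p, 0.45, times, seed = 1,
                              engine = if (beta_p > 0) "plastic" else "static")
    hit <- which(abs(pos[1, 1, ] - 0.3) < tol)
    if (length(hit)) times[min(hit)] else Inf
  }
  expect_gte(time_to_reach(5), time_to_reach(0))
})

test_that("reflecting boundaries keep every position on the line", {
  flat <- drift_landscape(0)
  p <- dynamics_params(beta = 0, sigma = 0.9, t0 = 0)
  pos <- simulate_landscape(flat, p, c(0.02, 0.98), seq(0, 20, by = 1),
                            n_runs = 200, seed = 5)
  expect_true(all(pos >= 0 & pos <= 1))
})

test_that("inter-trial decay blends landscapes element-wise", {
  expect_equal(apply_intertrial_decay(rep(0, 5), rep(1, 5), 1), rep(0, 5))
  expect_equal(apply_intertrial_decay(rep(0, 5), rep(1, 5), 0), rep(1, 5))
  expect_equal(apply_intertrial_decay(rep(0, 5), rep(1, 5), 0.8), rep(0.2, 5))
  expect_error(apply_intertrial_decay(rep(0, 5), rep(1, 4), 0.5), "length")
})

test_that("carry-over pulls the next trial toward the previous response", {
  tw <- two_well_landscape()
  # deterministic paired simulation: nearby target, sigma = 0
  p_carry <- params_plastic_fit(sigma = 0, lambda_t = 0.2)
  p_reset <- params_plastic_fit(sigma = 0, lambda_t = 1)
  tg <- c(0.42, 0.5)
  carry <- simulate_trial_sequence(tw, p_carry, tg, c(6, 6), seed = 1)
  reset <- simulate_trial_sequence(tw, p_reset, tg, c(6, 6), seed = 1)
  expect_identical(carry$response[1], reset$response[1])
  d_carry <- abs(carry$response[2] - carry$response[1])
  d_reset <- abs(reset$response[2] - reset$response[1])
  expect_lt(d_carry, d_reset)
})

test_that("attractor comparison: continuous beats discrete in the noiseless limit", {
  res <- attractor_comparison(
    sigma_levels = 0, beta_p_levels = 0,
    params = params_plastic_fit(lambda_t = 1),
    trials_per_rep = 40L, n_reps = 2L, seed = 3
  )
  flat <- res[res$landscape == "continuous", ]
  well <- res[res$landscape == "discrete", ]
  expect_true(all(flat$mse == 0))
  expect_gt(well$mse[well$delay_s == 20], 0)
})
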