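test_that("noise-free flat-landscape model distributions are point masses", {
  flat <- drift_landscape(0)
  p <- dynamics_params(beta = 0.1, sigma = 0, t0 = 1.5, beta_p = 0)
  ms <- simulate_model_distributions(flat, p, delays = c(0, 20),
                                     n_starts = 10, n_runs = 5, seed = 1)
  sums <- apply(unclass(ms), c(2, 3), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  centers <- attr(ms, "error_centers")
  zero_bin <- which.min(abs(centers))
  for (di in 1:2) for (si in 1:10) {
    expect_gt(sum(ms[(zero_bin - 1):(zero_bin + 1), si, di]), 0.99)
  }
})

test_that("model dispersion grows with the noise parameter", {
  tw <- two_well_landscape()
  sds <- vapply(c(0.05, 0.1, 0.18), function(s) {
    p <- dynamics_params(beta = 0.05, sigma = s, t0 = 1.5)
    ms <- simulate_model_distributions(tw, p, delays = 20, n_starts = 5,
                                       n_runs = 100, seed = 2)
    centers <- attr(ms, "error_centers")
    mean(vapply(1:5, function(si) {
      pr <- ms[, si, 1]
      mu <- sum(pr * centers)
      sqrt(sum(pr * (centers - mu)^2))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(sds) > 0))
})

test_that("KL cost is a proper divergence with the printed hand value", {
  set.seed(3)
  arr <- array(stats::rexp(50 * 4 * 2), dim = c(50, 4, 2))
  arr <- sweep(arr, c(2, 3), apply(arr, c(2, 3), sum), "/")
  ds <- response_distribution_set(arr, seq(-0.245, 0.245, length.out = 50),
                                  seq(0.1, 0.9, length.out = 4), c(1, 20))
  expect_lt(kl_cost(ds, ds), 1e-4)
  arr2 <- array(stats::rexp(50 * 4 * 2), dim = c(50, 4, 2))
  arr2 <- sweep(arr2, c(2, 3), apply(arr2, c(2, 3), sum), "/")
  ds2 <- response_distribution_set(arr2, attr(ds, "error_centers"),
                                   attr(ds, "target_centers"), c(1, 20))
  expect_gte(kl_cost(ds, ds2), 0)

  # hand computation: p = (.5,.5), q = (.9,.1)
  mk <- function(v) response_distribution_set(array(v, dim = c(2, 1, 1)),
                                              c(-0.1, 0.1), 0.5, 1)
  expect_equal(kl_cost(mk(c(0.5, 0.5)), mk(c(0.9, 0.1))),
               0.5 * log(0.5 / 0.9) + 0.5 * log(0.5 / 0.1),
               tolerance = 1e-4)
})

test_that("pattern search minimizes a bowl within its box", {
  fn <- function(x) sum((x - c(0.3, -0.2))^2)
  res <- pattern_search <- memscape:::pattern_search(
    c(0, 0), fn, lower = c(-1, -1), upper = c(1, 1),
    step0 = 0.25, min_step = 1e-4, max_evals = 500
  )
  expect_equal(res$par, c(0.3, -0.2), tolerance = 1e-3)
  expect_true(all(res$par >= -1 & res$par <= 1))
  # box binding: optimum outside the box lands on the boundary
  res2 <- memscape:::pattern_search(c(0, 0), function(x) sum((x - 2)^2),
                                    lower = c(-1, -1), upper = c(1, 1),
                                    step0 = 0.25, min_step = 1e-4,
                                    max_evals = 500)
  expect_equal(res2$par, c(1, 1), tolerance = 1e-6)
})

test_that("the generating parameters beat a 50% perturbation under shared noise", {
  tw <- two_well_landscape()
  p_true <- dynamics_params(beta = 0.1, sigma = 0.1, t0 = 1.5)
  data_set <- simulate_model_distributions(tw, p_true, n_starts = 20,
                                           n_runs = 40, seed = 10,
                                           smooth_stencil = FALSE)
  z <- memscape:::noise_matrix(77, 20 * 40, 250)
  cost_at <- function(p) {
    ms <- simulate_model_distributions(tw, p, n_starts = 20, n_runs = 40,
                                       noise = z)
    kl_cost(data_set, ms)
  }
  p_pert <- dynamics_params(beta = 0.15, sigma = 0.15, t0 = 1.5)
  expect_lt(cost_at(p_true), cost_at(p_pert))
})

test_that("a small frozen-landscape fit recovers the dynamics and stays in bounds", {
  tw <- two_well_landscape()
  p_true <- dynamics_params(beta = 0.12, sigma = 0.09, t0 = 1.5)
  data_set <- simulate_model_distributions(tw, p_true, n_starts = 25,
                                           n_runs = 40, seed = 20,
                                           smooth_stencil = FALSE)
  cfg <- fit_config(model = "static", n_starts = 25, n_runs = 40,
                    fit_drift = FALSE, fit_t0 = FALSE,
                    max_evals_phase1 = 40, max_evals_phase2 = 20,
                    min_step = 0.01, seed = 21)
  fit <- fit_landscape_model(data_set, cfg, init_landscape = tw,
                             init_params = dynamics_params(beta = 0.1,
                                                           sigma = 0.1,
                                                           t0 = 1.5))
  b <- param_bounds()
  expect_gte(fit$params$beta, b$lower[b$name == "beta"])
  expect_lte(fit$params$beta, b$upper[b$name == "beta"])
  expect_gte(fit$params$sigma, b$lower[b$name == "sigma"])
  expect_lte(fit$params$sigma, b$upper[b$name == "sigma"])
  expect_true(fit$converged)
  expect_equal(fit$params$beta, 0.12, tolerance = 0.35)
  expect_equal(fit$params$sigma, 0.09, tolerance = 0.35)
  expect_lt(fit$cost, fit$trace[1])
})

test_that("the plastic model with zero plastic weight scores like the static model", {
  tw <- two_well_landscape()
  p0 <- dynamics_params(beta = 0.08, sigma = 0.08, t0 = 1.5, beta_p = 0)
  a <- simulate_model_distributions(tw, p0, delays = c(1, 20), n_starts = 10,
                                    n_runs = 20, seed = 30)
  b <- simulate_model_distributions(tw, p0, delays = c(1, 20), n_starts = 10,
                                    n_runs = 20, seed = 30)
  expect_identical(unclass(a), unclass(b))
})

test_that("bias meta cost matches hand computations", {
  expect_equal(bias_meta_cost(0.02, 0.04, 1, 1), 0.0004 / 0.04)
  expect_equal(bias_meta_cost(c(0.02, 0.03), c(0.02, 0.03), 2, 2), 0)
  # strictly increasing in the time-constant gap
  costs <- vapply(c(0, 0.5, 1, 2), function(d) {
    bias_meta_cost(0.02, 0.02, 1 + d, 1)
  }, numeric(1))
  expect_true(all(diff(costs) > 0))
})

test_that("log-likelihood counts trials against the right model bins", {
  arr <- array(1 / 50, dim = c(50, 50, 6))
  uni <- response_distribution_set(arr, seq(-0.245, 0.245, length.out = 50),
                                   seq(0.1, 0.9, length.out = 50),
                                   task_delays())
  set.seed(40)
  tg <- runif(200, 0.1, 0.9)
  tr <- make_trials(tg, tg + rnorm(200, 0, 0.03),
                    delays = sample(task_delays(), 200, replace = TRUE))
  ll <- log_likelihood(uni, tr)
  expect_equal(as.numeric(ll), 200 * log(1 / 50), tolerance = 1e-10)
  expect_equal(attr(ll, "n"), 200L)

  # a matched model dominates a mismatched one on its own data
  tw <- two_well_landscape()
  p_true <- dynamics_params(beta = 0.1, sigma = 0.08, t0 = 1.5)
  ms_true <- simulate_model_distributions(tw, p_true, n_starts = 25,
                                          n_runs = 60, seed = 41)
  p_off <- dynamics_params(beta = 0.03, sigma = 0.18, t0 = 1.5)
  ms_off <- simulate_model_distributions(tw, p_off, n_starts = 25,
                                         n_runs = 60, seed = 41)
  set.seed(42)
  tg <- runif(2000, 0.1, 0.9)
  dl <- task_delays()[sample.int(6, 2000, replace = TRUE)]
  resp <- vapply(seq_len(2000), function(i) {
    as.numeric(simulate_landscape(tw, p_true, tg[i], p_true$t0 + dl[i],
                                  seed = 1000 + i))
  }, numeric(1))
  tr2 <- make_trials(tg, resp, delays = dl)
  expect_gt(as.numeric(log_likelihood(ms_true, tr2)),
            as.numeric(log_likelihood(ms_off, tr2)))
})

test_that("information criteria follow their definitions", {
  expect_equal(aic_bic(-10, 0, 100)$aic, 20)
  expect_equal(aic_bic(0, 1, exp(2))$bic, 2)
  set.seed(50)
  for (i in 1:5) {
    ll <- rnorm(1); k <- sample(1:60, 1); n <- sample(10:10000, 1)
    ic <- aic_bic(ll, k, n)
    expect_equal(ic$aic - ic$bic, 2 * k - k * log(n), tolerance = 1e-12)
  }
})

test_that("model comparison is calibrated for twins and decisive for separated models", {
  arr <- array(1 / 50, dim = c(50, 50, 6))
  centers_e <- seq(-0.245, 0.245, length.out = 50)
  centers_t <- seq(0.1, 0.9, length.out = 50)
  mkset <- function(a) response_distribution_set(a, centers_e, centers_t,
                                                 task_delays())
  set.seed(60)
  tg <- runif(400, 0.1, 0.9)
  tr <- make_trials(tg, tg + rnorm(400, 0, 0.04),
                    delays = sample(task_delays(), 400, replace = TRUE))

  # literally identical models: every resample ties, p sits at one half
  tw <- two_well_landscape()
  p <- dynamics_params(beta = 0.1, sigma = 0.08, t0 = 1.5)
  twin <- simulate_model_distributions(tw, p, n_starts = 15, n_runs = 30,
                                       seed = 61)
  cmp <- compare_models(list(model_set = twin, k = 53),
                        list(model_set = twin, k = 53),
                        tr, n_boot = 400, seed = 63)
  expect_equal(cmp$p_aic, 0.5)

  # decisive: model concentrated on the data errors vs concentrated away
  good <- array(1e-9, dim = c(50, 50, 6))
  good[24:27, , ] <- 1
  bad <- array(1e-9, dim = c(50, 50, 6))
  bad[44:47, , ] <- 1
  norm3 <- function(a) sweep(a, c(2, 3), apply(a, c(2, 3), sum), "/")
  cmp2 <- compare_models(list(model_set = mkset(norm3(good)), k = 53),
                         list(model_set = mkset(norm3(bad)), k = 53),
                         tr, n_boot = 1000, seed = 64)
  expect_equal(cmp2$p_aic, 0.001)
  expect_equal(cmp2$p_aic_label, "<0.001")
  expect_gt(cmp2$p_aic, 0)  # floor honored, never exactly zero
})

test_that("robustness scan varies one parameter at a time around the fit", {
  tw <- two_well_landscape()
  p <- params_plastic_fit(beta_p = 5, sigma_p = 0.03)
  fit <- structure(
    list(landscape = tw, params = p, cost = 1, k = 55,
         config = fit_config(model = "plastic", seed = 1)),
    class = "landscape_fit"
  )
  ds <- simulate_model_distributions(tw, p, delays = c(1, 20), n_starts = 5,
                                     n_runs = 10, seed = 70,
                                     smooth_stencil = FALSE)
  scan <- robustness_scan(fit, ds, n_values = 4, n_reps = 3,
                          n_starts = 5, n_runs = 10, seed = 71)
  expect_setequal(unique(scan$parameter), c("beta_p", "sigma_p"))
  expect_true(any(scan$is_fitted[scan$parameter == "beta_p"]))
  expect_true(any(scan$is_fitted[scan$parameter == "sigma_p"]))
  expect_true(all(scan$sd_loss >= 0))
  b <- param_bounds()
  bp <- scan$value[scan$parameter == "beta_p"]
  expect_true(all(bp >= b$lower[b$name == "beta_p"] &
                    bp <= b$upper[b$name == "beta_p"]))
})
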