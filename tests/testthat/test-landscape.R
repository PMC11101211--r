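test_that("drift interpolation is exact at grid points and linear between", {
  flat <- drift_landscape(0)
  expect_equal(drift_at(flat, c(0, 0.37, 1)), c(0, 0, 0))

  lin <- drift_landscape(0.5 - seq(0, 1, length.out = 50), smoothing_width = 0)
  expect_equal(drift_at(lin, 0.5), 0, tolerance = 1e-12)
  expect_equal(drift_at(lin, lin$grid), lin$drift)
  expect_error(drift_at(lin, 1.2), "\\[0, 1\\]")
})

test_that("two-well drift vanishes at the wells with a stabilizing sign change", {
  tw <- two_well_landscape(centers = c(0.3, 0.7))
  # brute-force sign scan on a 10x finer grid around each center
  for (ctr in c(0.3, 0.7)) {
    xs <- seq(ctr - 0.02, ctr + 0.02, length.out = 21)
    g <- drift_at(tw, xs)
    expect_lt(abs(drift_at(tw, ctr)), 1 / 49)  # below grid resolution
    expect_true(all(g[xs < ctr - 0.005] > 0))   # pushes up toward the well
    expect_true(all(g[xs > ctr + 0.005] < 0))   # pushes down toward the well
  }
  # the barrier crossing is destabilizing
  expect_true(drift_at(tw, 0.52) > 0 || drift_at(tw, 0.48) < 0)
})

test_that("energy is the negative antiderivative of drift", {
  flat <- drift_landscape(0)
  expect_equal(energy_from_drift(flat), rep(0, 50))

  lin <- drift_landscape(0.5 - seq(0, 1, length.out = 50), smoothing_width = 0)
  e <- energy_from_drift(lin)
  # independent quadrature oracle
  skip_if_not_installed("pracma")
  e_oracle <- -pracma::cumtrapz(lin$grid, lin$drift)[, 1]
  e_oracle <- e_oracle - min(e_oracle)
  expect_equal(e, e_oracle, tolerance = 1e-12)
  # analytic: quadratic with minimum at 0.5
  expect_equal(which.min(e), 25, tolerance = 1)
  expect_equal(e - min(e), (lin$grid - 0.5)^2 / 2 - min((lin$grid - 0.5)^2 / 2),
               tolerance = 1e-3)

  # antisymmetric drift about 0.5 gives symmetric energy
  tw <- two_well_landscape(centers = c(0.3, 0.7))
  e2 <- energy_from_drift(tw)
  expect_equal(e2, rev(e2), tolerance = 1e-10)
})

test_that("drift/energy round trip is exact under trapezoid inversion", {
  set.seed(1)
  d <- stats::rnorm(50)
  ls <- drift_landscape(d, smoothing_width = 0)
  e <- energy_from_drift(ls)
  d_rec <- drift_from_energy(e, ls$grid, drift0 = d[1])
  expect_lt(max(abs(d_rec[2:49] - d[2:49])) / max(abs(d[2:49])), 1e-6)
})

test_that("Gaussian smoothing preserves constant profiles exactly", {
  ls <- drift_landscape(rep(3.7, 50), smoothing_width = 0.05)
  expect_equal(ls$drift_smooth, rep(3.7, 50), tolerance = 1e-12)
})

test_that("two-well construction is antisymmetric with the right extrema", {
  tw <- two_well_landscape(centers = c(0.3, 0.7))
  expect_equal(tw$drift, -rev(tw$drift), tolerance = 1e-10)
  # extrema scan on a 10x refined grid: exactly 2 minima, 1 interior maximum
  fine <- two_well_landscape(centers = c(0.3, 0.7), n_grid = 500L)
  e <- energy_from_drift(fine)
  # count strict slope-sign changes, ignoring flat numerical plateaus
  s <- sign(diff(e))
  s <- s[s != 0]
  runs <- rle(s)$values
  n_minima <- sum(runs[-length(runs)] == -1 & runs[-1] == 1)
  n_maxima <- sum(runs[-length(runs)] == 1 & runs[-1] == -1)
  expect_equal(n_minima, 2L)
  expect_equal(n_maxima, 1L)
  expect_equal(fine$grid[which.min(e[fine$grid < 0.5])], 0.3, tolerance = 0.01)
  expect_equal(fine$grid[fine$grid > 0.5][which.min(e[fine$grid > 0.5])], 0.7,
               tolerance = 0.01)
  expect_error(two_well_landscape(centers = c(0.5, 0.5)), "distinct")
})

test_that("landscape and params serialization round-trip at full precision", {
  set.seed(2)
  ls <- drift_landscape(stats::rnorm(50), smoothing_width = 0.0314159)
  path <- withr::local_tempfile(fileext = ".txt")
  write_landscape(ls, path)
  ls2 <- read_landscape(path)
  expect_equal(ls2$drift, ls$drift, tolerance = 1e-15)
  expect_equal(ls2$smoothing_width, ls$smoothing_width, tolerance = 1e-15)

  p <- params_plastic_fit(lambda_t = 0.8)
  pp <- withr::local_tempfile(fileext = ".cfg")
  write_params(p, pp)
  p2 <- read_params(pp)
  for (k in c("beta", "sigma", "dt", "t0", "beta_p", "sigma_p", "lambda_t")) {
    expect_equal(p2[[k]], p[[k]], tolerance = 1e-15)
  }
})

test_that("dynamics parameter validation catches bad inputs", {
  expect_error(dynamics_params(dt = 0), "dt")
  expect_error(dynamics_params(sigma = -0.1), "sigma")
  expect_error(dynamics_params(beta_p = 1, sigma_p = 0), "sigma_p")
  expect_error(dynamics_params(lambda_t = 1.2), "lambda_t")
})
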