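test_that("generated targets are uniform on the task range", {
  spec <- ground_truth_spec(
    landscape = drift_landscape(0),
    params = dynamics_params(beta = 0, sigma = 0, t0 = 0.5),
    n_participants = 50, trials_per_participant = 100,
    inattentive_frac = 0, seed = 1
  )
  tr <- generate_dataset(spec)
  expect_gte(nrow(tr), 5000)
  ks <- suppressWarnings(stats::ks.test(tr$target, "punif", 0.1, 0.9))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(tr$delay_s %in% task_delays()))
  # each participant uses exactly two delays
  per <- tapply(tr$delay_s, tr$participant, function(d) length(unique(d)))
  expect_true(all(per <= 2))
})

test_that("datasets regenerate bit-for-bit from the spec seed", {
  spec <- ground_truth_spec(n_participants = 4, trials_per_participant = 20,
                            seed = 9)
  a <- generate_dataset(spec)
  b <- generate_dataset(spec)
  expect_identical(a, b)
  spec2 <- ground_truth_spec(n_participants = 4, trials_per_participant = 20,
                             seed = 10)
  expect_false(identical(generate_dataset(spec2)$response, a$response))
})

test_that("noise-free reset dynamics make responses a function of target and delay", {
  tw <- two_well_landscape()
  p <- dynamics_params(beta = 0.1, sigma = 0, t0 = 1, lambda_t = 1, beta_p = 0)
  tg <- c(0.25, 0.25, 0.6, 0.6)
  dl <- c(6, 6, 20, 20)
  sim <- simulate_trial_sequence(tw, p, tg, dl, seed = 3)
  expect_equal(sim$response[1], sim$response[2])
  expect_equal(sim$response[3], sim$response[4])
})

test_that("the attention filter removes exactly the injected inattentive trials", {
  # constructed closure: low noise keeps model errors far below threshold
  spec <- ground_truth_spec(
    landscape = drift_landscape(0),
    params = dynamics_params(beta = 0, sigma = 0.02, t0 = 0.5),
    n_participants = 10, trials_per_participant = 50,
    inattentive_frac = 0.1, seed = 5
  )
  tr <- generate_dataset(spec)
  expect_true(all(abs(tr$response - tr$target)[tr$inattentive] > 0.25))
  expect_true(all(tr$response >= 0 & tr$response <= 1))
  kept <- attention_filter(tr)
  expect_equal(attr(kept, "n_removed"), sum(tr$inattentive))
  expect_true(all(!kept$inattentive))
})

test_that("plastic carry-over produces a PI range above the reset noise floor", {
  tw <- two_well_landscape()
  gen <- function(lt) generate_dataset(ground_truth_spec(
    landscape = tw, params = params_plastic_fit(lambda_t = lt),
    delays = 20, n_participants = 30, trials_per_participant = 60,
    delays_per_participant = 1, inattentive_frac = 0, seed = 11
  ))
  pc_plastic <- pi_spatial(gen(0.8), 20, n_boot = 100, seed = 12)
  pc_reset <- pi_spatial(gen(1.0), 20, n_boot = 100, seed = 12)
  expect_gt(pc_plastic$range, pc_reset$range)
  # attraction toward the previous response: rising curve through zero offset
  mid <- abs(pc_plastic$curve$offset) <= 0.15
  slope <- stats::coef(stats::lm(pc_plastic$curve$estimate[mid] ~
                                   pc_plastic$curve$offset[mid]))[2]
  expect_gt(slope, 0)
})

test_that("the recovery grid spans its mesh inside the search bounds", {
  cells <- generate_recovery_grid(n_noise = 2, n_drift = 3,
                                  runs_per_cell = 5, n_starts = 10, seed = 13)
  expect_length(cells, 6L)
  b <- param_bounds()
  for (cell in cells) {
    expect_gte(cell$params$sigma, b$lower[b$name == "sigma"])
    expect_lte(cell$params$sigma, b$upper[b$name == "sigma"])
    expect_gte(cell$params$beta, b$lower[b$name == "beta"])
    expect_lte(cell$params$beta, b$upper[b$name == "beta"])
    expect_equal(nrow(cell$trials), 10 * 5 * 6)
  }
  # dispersion at 20 s grows with the noise parameter at fixed drift
  grid <- attr(cells, "grid")
  lo <- which(grid$sigma == min(grid$sigma) & grid$beta == min(grid$beta))
  hi <- which(grid$sigma == max(grid$sigma) & grid$beta == min(grid$beta))
  disp <- function(cell) {
    tr <- cell$trials[cell$trials$delay_s == 20, ]
    stats::sd(tr$response - tr$target)
  }
  expect_gt(disp(cells[[hi]]), disp(cells[[lo]]))
})
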