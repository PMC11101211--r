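#' Ground-truth specification for a synthetic behavioral dataset
#'
#' Everything needed to regenerate a dataset bit-for-bit: the generating
#' landscape and dynamics, the task structure (delays, participants,
#' trials per participant) and the inattention model. Defaults emulate
#' the behavioral study: 161 participants with about 110 trials each
#' (roughly 17,760 trials in total), uniform targets on `[0.1, 0.9]`,
#' two of the six task delays per participant, and ~1.2% inattentive
#' trials whose absolute error exceeds the 0.25 attention threshold.
#'
#' @param landscape Generating [drift_landscape()] (default: the
#'   idealized two-well landscape).
#' @param params Generating [dynamics_params()].
#' @param delays Task delay set.
#' @param n_participants Number of participants.
#' @param trials_per_participant Trials per participant.
#' @param delays_per_participant Distinct delays assigned to each
#'   participant (default 2, as in the task design).
#' @param inattentive_frac Fraction of trials replaced by inattentive
#'   responses (error magnitude above 0.25).
#' @param seed Root seed.
#' @return A list of class `ground_truth_spec`.
#' @export
ground_truth_spec <- function(landscape = two_well_landscape(),
                              params = params_static_fit(),
                              delays = task_delays(),
                              n_participants = 161L,
                              trials_per_participant = 110L,
                              delays_per_participant = 2L,
                              inattentive_frac = 0.012,
                              seed = 1L) {
  if (inattentive_frac < 0 || inattentive_frac >= 1) {
    stop("`inattentive_frac` must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(landscape = landscape, params = params, delays = delays,
         n_participants = n_participants,
         trials_per_participant = trials_per_participant,
         delays_per_participant = delays_per_participant,
         inattentive_frac = inattentive_frac, seed = seed),
    class = "ground_truth_spec"
  )
}

#' Generate a synthetic trial table
#'
#' Simulates every participant as an ordered sequence of trials through
#' [simulate_trial_sequence()], so inter-trial structure (proactive
#' interference when `lambda_t < 1` and `beta_p > 0`) is present in the
#' data. Targets are i.i.d. uniform on `[0.1, 0.9]`; each participant
#' draws a fixed subset of the task delays and samples among them per
#' trial. Inattentive trials are injected by replacing the response with
#' `target + sign * (0.25 + |U(0, 0.25)|)`, with the sign chosen so the
#' response stays on the line; their error magnitude always exceeds the
#' 0.25 attention threshold, so [attention_filter()] removes exactly
#' these trials whenever the model's own errors stay below threshold.
#'
#' @param spec A [ground_truth_spec()].
#' @return A trial table tibble with columns `participant`, `order`,
#'   `target`, `response`, `delay_s`, `skipped`, `inattentive`.
#' @examples
#' spec <- ground_truth_spec(n_participants = 3, trials_per_participant = 10)
#' generate_dataset(spec)
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "ground_truth_spec"))
  purrr::map_dfr(seq_len(spec$n_participants), function(p) {
    set.seed(derive_seed(spec$seed, p, 1))
    n <- spec$trials_per_participant
    own_delays <- spec$delays[sample.int(
      length(spec$delays),
      min(spec$delays_per_participant, length(spec$delays))
    )]
    targets <- stats::runif(n, 0.1, 0.9)
    trial_delays <- own_delays[sample.int(length(own_delays), n, replace = TRUE)]
    inattentive <- stats::runif(n) < spec$inattentive_frac
    inatt_mag <- 0.25 + abs(stats::runif(n, 0, 0.25))
    inatt_sign_pref <- sample(c(-1, 1), n, replace = TRUE)

    sim <- simulate_trial_sequence(spec$landscape, spec$params,
                                   targets, trial_delays,
                                   seed = derive_seed(spec$seed, p, 2))
    response <- sim$response
    if (any(inattentive)) {
      for (i in which(inattentive)) {
        sgn <- inatt_sign_pref[i]
        if (targets[i] + sgn * inatt_mag[i] < 0 ||
            targets[i] + sgn * inatt_mag[i] > 1) {
          sgn <- -sgn
        }
        response[i] <- targets[i] + sgn * inatt_mag[i]
      }
    }
    tibble::tibble(
      participant = sprintf("P%03d", p),
      order = seq_len(n),
      target = targets,
      response = response,
      delay_s = trial_delays,
      skipped = FALSE,
      inattentive = inattentive
    )
  })
}

#' Parameter grid for the fitting-procedure recovery study
#'
#' Builds one synthetic dataset per cell of an (noise, drift-strength)
#' mesh on the idealized two-well landscape: each cell simulates
#' `n_starts` equally spaced starting positions with `runs_per_cell`
#' runs each, sampled at the task delays, mirroring the design used to
#' validate the fitting procedure. Grid values sit inside the fitted
#' parameter range.
#'
#' @param n_noise,n_drift Grid sizes (default 10 x 10).
#' @param sigma_range,beta_range Ranges the grids span (within the
#'   fitting bounds, centered on the region the fitted values occupy).
#' @param runs_per_cell Runs per starting position (default 50).
#' @param n_starts Starting positions (default 50).
#' @param landscape Generating landscape.
#' @param t0 Encoding delay used for every cell.
#' @param delays Task delays sampled.
#' @param seed Root seed.
#' @return A list with one element per cell: `params` (true
#'   [dynamics_params()]) and `trials` (tibble `target`, `response`,
#'   `delay_s` with one row per (start, run, delay)).
#' @export
generate_recovery_grid <- function(n_noise = 10L, n_drift = 10L,
                                   sigma_range = c(0.05, 0.18),
                                   beta_range = c(0.05, 0.18),
                                   runs_per_cell = 50L, n_starts = 50L,
                                   landscape = two_well_landscape(),
                                   t0 = 1.5, delays = task_delays(),
                                   seed = 1L) {
  sigmas <- seq(sigma_range[1], sigma_range[2], length.out = n_noise)
  betas <- seq(beta_range[1], beta_range[2], length.out = n_drift)
  starts <- seq(0.1, 0.9, length.out = n_starts)
  cells <- tidyr::expand_grid(sigma = sigmas, beta = betas)
  out <- purrr::pmap(cells, function(sigma, beta) {
    p <- dynamics_params(beta = beta, sigma = sigma, t0 = t0, beta_p = 0)
    cell_seed <- derive_seed(seed, round(sigma * 1e4) %% 131070,
                             round(beta * 1e4) %% 131070)
    pos <- simulate_landscape(landscape, p, starts, p$t0 + sort(delays),
                              n_runs = runs_per_cell, seed = cell_seed)
    grid_df <- tidyr::expand_grid(
      delay_s = sort(delays),
      run = seq_len(runs_per_cell),
      target = starts
    )
    trials <- tibble::tibble(
      target = grid_df$target,
      response = as.numeric(pos),
      delay_s = grid_df$delay_s
    )
    list(params = p, trials = trials, seed = cell_seed)
  })
  attr(out, "grid") <- cells
  out
}
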