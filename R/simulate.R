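#' Derivative-of-Gaussian plasticity kernel
#'
#' The per-step perturbation added to the drift profile by the plastic
#' model: the drift signature of a Gaussian depression carved into the
#' energy landscape at the current position of the memory trace,
#' `zeta_P(x) = (x0 - x) * exp(-(x0 - x)^2 / (2 * sigma_p^2))`.
#' Adding `zeta_P` to the drift corresponds to subtracting a Gaussian from
#' the energy, so the perturbation is attractive: positions just below
#' `x0` are pushed up toward it and positions just above are pushed down.
#' No normalization is applied, so the kernel amplitude scales with
#' `sigma_p`: its extrema sit at `x0 +/- sigma_p` with magnitude
#' `sigma_p * exp(-1/2)`.
#'
#' @param x0 Center position(s) in `[0, 1]` (the memory trace).
#' @param grid Grid positions at which to evaluate the kernel.
#' @param sigma_p Kernel width in line units (> 0).
#' @return If `x0` is scalar, a vector over `grid`; otherwise a matrix
#'   with one row per center.
#' @export
plastic_kernel <- function(x0, grid, sigma_p) {
  if (!is.numeric(sigma_p) || sigma_p <= 0) {
    stop("`sigma_p` must be positive", call. = FALSE)
  }
  d <- outer(x0, grid, "-")
  k <- d * exp(-d^2 / (2 * sigma_p^2))
  if (length(x0) == 1L) as.numeric(k) else k
}

#' Blend the static landscape with the previous trial's final landscape
#'
#' Inter-trial decay of plasticity: the drift profile at the start of a
#' trial is the convex combination
#' `lambda_t * static + (1 - lambda_t) * final`, so `lambda_t = 1` resets
#' the landscape completely and `lambda_t = 0` carries the deformation
#' over unchanged.
#'
#' @param static_drift Drift values of the static landscape.
#' @param final_drift Final (deformed) drift values of the previous trial.
#' @param lambda_t Decay weight in `[0, 1]`.
#' @return Numeric drift vector for the next trial.
#' @export
apply_intertrial_decay <- function(static_drift, final_drift, lambda_t) {
  if (length(static_drift) != length(final_drift)) {
    stop("drift vectors must have the same length", call. = FALSE)
  }
  if (lambda_t < 0 || lambda_t > 1) {
    stop("`lambda_t` must lie in [0, 1]", call. = FALSE)
  }
  lambda_t * static_drift + (1 - lambda_t) * final_drift
}

# Standard-normal noise with one deterministic substream per trajectory:
# column j of the result depends only on (seed, j), so adding trajectories
# or truncating steps never alters earlier streams.
noise_matrix <- function(seed, n_traj, n_steps) {
  z <- matrix(0, nrow = n_steps, ncol = n_traj)
  for (j in seq_len(n_traj)) {
    set.seed(derive_seed(seed, j))
    z[, j] <- stats::rnorm(n_steps)
  }
  z
}

#' Simulate memory-trace trajectories on a landscape
#'
#' Euler integration of the drift–diffusion dynamics
#' `x <- x + (beta * G(x) + eps) * dt` with reflecting boundaries at 0 and
#' 1. When `beta_p > 0` (plastic model) each trajectory carries its own
#' copy of the drift profile, and after every step a
#' [plastic_kernel()] centered at the updated position is added to it,
#' scaled by `beta_p * dt`. With `beta_p = 0` the plastic engine adds a
#' zero perturbation and reproduces the static engine exactly, trajectory
#' by trajectory.
#'
#' Time is internal simulation time measured from trial onset: a task
#' delay `d` corresponds to recording time `params$t0 + d`. If encoding
#' parameters `beta_enc` / `sigma_enc` are set they govern steps before
#' `t0`; plasticity accrues throughout, including the encoding period.
#'
#' @param landscape A [drift_landscape()].
#' @param params A [dynamics_params()].
#' @param start_positions Starting positions in `[0, 1]`.
#' @param record_times Internal times (seconds, sorted, non-negative) at
#'   which to record positions.
#' @param n_runs Independent runs per start.
#' @param seed Root seed; each (start, run) trajectory uses its own
#'   deterministic substream.
#' @param engine `"auto"` (static when `beta_p == 0`), `"static"`, or
#'   `"plastic"` to force the per-trajectory-landscape code path.
#' @param noise Optional pre-drawn standard-normal matrix
#'   (`n_steps x n_traj`) for common-random-number cost evaluations;
#'   overrides `seed`.
#' @param return_drift Also return the final drift profile of every
#'   trajectory (plastic engine only).
#' @return A 3-d array `positions[start, run, time]` with attribute
#'   `record_times`; if `return_drift = TRUE`, a list with `positions`
#'   and `final_drift` (matrix `n_traj x n_grid`, trajectories ordered
#'   run-major: all starts for run 1, then run 2, ...).
#' @examples
#' tw <- two_well_landscape()
#' p <- params_static_fit()
#' sim <- simulate_landscape(tw, p, start_positions = c(0.2, 0.6),
#'                           record_times = p$t0 + c(0, 20), n_runs = 10,
#'                           seed = 1)
#' dim(sim)
#' @export
simulate_landscape <- function(landscape, params, start_positions, record_times,
                               n_runs = 1L, seed = 1L,
                               engine = c("auto", "static", "plastic"),
                               noise = NULL, return_drift = FALSE) {
  engine <- match.arg(engine)
  if (length(start_positions) == 0L) stop("`start_positions` is empty", call. = FALSE)
  if (any(start_positions < 0 | start_positions > 1)) {
    stop("start positions must lie in [0, 1]", call. = FALSE)
  }
  if (any(record_times < 0) || is.unsorted(record_times)) {
    stop("`record_times` must be sorted and non-negative", call. = FALSE)
  }
  if (n_runs < 1L) stop("`n_runs` must be at least 1", call. = FALSE)
  d0 <- landscape$drift_smooth
  if (any(!is.finite(d0))) stop("landscape drift contains non-finite values", call. = FALSE)

  plastic <- switch(engine,
    auto = params$beta_p > 0,
    static = FALSE,
    plastic = TRUE
  )
  dt <- params$dt
  n_grid <- length(d0)
  h <- 1 / (n_grid - 1)
  n_start <- length(start_positions)
  n_traj <- n_start * n_runs
  rec_steps <- as.integer(round(record_times / dt))
  n_steps <- max(rec_steps)
  sqrt_scaling <- identical(params$noise_scaling, "sqrt_dt")
  noise_mult <- if (sqrt_scaling) sqrt(dt) else dt

  if (is.null(noise)) {
    z <- if (n_steps > 0) noise_matrix(seed, n_traj, n_steps) else
      matrix(0, 0, n_traj)
  } else {
    if (nrow(noise) < n_steps || ncol(noise) < n_traj) {
      stop("`noise` matrix is smaller than the simulation requires", call. = FALSE)
    }
    z <- noise
  }

  # run-major trajectory layout: traj j = (run - 1) * n_start + start
  x <- rep(start_positions, times = n_runs)
  if (plastic) {
    drift_mat <- matrix(d0, nrow = n_traj, ncol = n_grid, byrow = TRUE)
    traj_idx <- seq_len(n_traj)
    grid <- landscape$grid
  }

  out <- array(NA_real_, dim = c(n_start, n_runs, length(rec_steps)))
  hit <- rec_steps == 0L
  if (any(hit)) out[, , which(hit)] <- x

  has_enc <- is.finite(params$beta_enc) || is.finite(params$sigma_enc)
  for (k in seq_len(n_steps)) {
    t_now <- (k - 1) * dt
    if (has_enc && t_now < params$t0) {
      b <- if (is.finite(params$beta_enc)) params$beta_enc else params$beta
      s <- if (is.finite(params$sigma_enc)) params$sigma_enc else params$sigma
    } else {
      b <- params$beta
      s <- params$sigma
    }
    idx <- pmin(floor(x / h), n_grid - 2)
    frac <- x / h - idx
    if (plastic) {
      g <- drift_mat[cbind(traj_idx, idx + 1)] * (1 - frac) +
        drift_mat[cbind(traj_idx, idx + 2)] * frac
    } else {
      g <- d0[idx + 1] * (1 - frac) + d0[idx + 2] * frac
    }
    if (sqrt_scaling) {
      x <- x + b * g * dt + s * z[k, seq_len(n_traj)] * noise_mult
    } else {
      x <- x + (b * g + s * z[k, seq_len(n_traj)]) * dt
    }
    x <- reflect01(x)
    if (plastic) {
      dxg <- outer(x, grid, "-")
      drift_mat <- drift_mat + (params$beta_p * dt) * (dxg * exp(-dxg^2 / (2 * params$sigma_p^2)))
    }
    hit <- rec_steps == k
    if (any(hit)) out[, , which(hit)] <- x
  }

  attr(out, "record_times") <- record_times
  if (return_drift) {
    fd <- if (plastic) drift_mat else
      matrix(d0, nrow = n_traj, ncol = n_grid, byrow = TRUE)
    return(list(positions = out, final_drift = fd))
  }
  out
}

#' Simulate a sequence of trials with inter-trial plasticity carry-over
#'
#' Runs the model through an ordered list of trials the way a participant
#' experiences them: the drift landscape at the start of each trial is the
#' [apply_intertrial_decay()] blend of the static landscape and the
#' previous trial's final (deformed) landscape, the trace is initialized
#' at the target, simulated for the encoding period plus the trial's
#' delay, and the final position is emitted as the response. With
#' `lambda_t = 1` trials are independent; with `lambda_t < 1` and
#' `beta_p > 0` the carry-over produces proactive interference.
#'
#' @param landscape Static [drift_landscape()].
#' @param params A [dynamics_params()] (its `lambda_t` sets the
#'   carry-over).
#' @param targets Target positions, in trial order.
#' @param delays Per-trial task delays in seconds.
#' @param seed Root seed; one substream per trial.
#' @param record_drift Keep the initial and final drift profile of every
#'   trial (list columns).
#' @return A tibble with columns `trial`, `target`, `delay_s`, `response`
#'   (plus `drift_initial` and `drift_final` list columns when requested).
#' @export
simulate_trial_sequence <- function(landscape, params, targets, delays,
                                    seed = 1L, record_drift = FALSE) {
  if (length(targets) != length(delays)) {
    stop("`targets` and `delays` must have the same length", call. = FALSE)
  }
  n_trials <- length(targets)
  d_static <- landscape$drift_smooth
  n_grid <- length(d_static)
  h <- 1 / (n_grid - 1)
  grid <- landscape$grid
  dt <- params$dt
  plastic <- params$beta_p > 0
  has_enc <- is.finite(params$beta_enc) || is.finite(params$sigma_enc)
  sqrt_scaling <- identical(params$noise_scaling, "sqrt_dt")

  responses <- numeric(n_trials)
  drift_init <- drift_fin <- if (record_drift) vector("list", n_trials) else NULL
  d_prev <- d_static

  for (tr in seq_len(n_trials)) {
    d_cur <- if (tr == 1L) d_static else
      apply_intertrial_decay(d_static, d_prev, params$lambda_t)
    if (record_drift) drift_init[[tr]] <- d_cur
    n_steps <- as.integer(round((params$t0 + delays[tr]) / dt))
    set.seed(derive_seed(seed, tr))
    z <- stats::rnorm(n_steps)
    x <- targets[tr]
    for (k in seq_len(n_steps)) {
      t_now <- (k - 1) * dt
      if (has_enc && t_now < params$t0) {
        b <- if (is.finite(params$beta_enc)) params$beta_enc else params$beta
        s <- if (is.finite(params$sigma_enc)) params$sigma_enc else params$sigma
      } else {
        b <- params$beta
        s <- params$sigma
      }
      idx <- min(floor(x / h), n_grid - 2)
      g <- d_cur[idx + 1] * (1 - (x / h - idx)) + d_cur[idx + 2] * (x / h - idx)
      x <- if (sqrt_scaling) x + b * g * dt + s * z[k] * sqrt(dt) else
        x + (b * g + s * z[k]) * dt
      x <- reflect01(x)
      if (plastic) {
        dxg <- x - grid
        d_cur <- d_cur + (params$beta_p * dt) * (dxg * exp(-dxg^2 / (2 * params$sigma_p^2)))
      }
    }
    responses[tr] <- x
    if (record_drift) drift_fin[[tr]] <- d_cur
    d_prev <- d_cur
  }

  out <- tibble::tibble(
    trial = seq_len(n_trials),
    target = as.numeric(targets),
    delay_s = as.numeric(delays),
    response = responses
  )
  if (record_drift) {
    out$drift_initial <- drift_init
    out$drift_final <- drift_fin
  }
  out
}

#' Compare memory accuracy of attractor systems over delay
#'
#' Simulates trial sequences on a continuous attractor (flat, zero-drift
#' landscape) and a discrete attractor (two-well landscape) at the
#' requested noise and plasticity levels, and reports the mean squared
#' error between response and target as a function of delay. Uniform
#' targets and sequential trials mean the accuracy penalty of proactive
#' interference is included whenever plasticity carries over
#' (`lambda_t < 1`).
#'
#' @param sigma_levels Noise strengths to simulate.
#' @param beta_p_levels Plasticity growth rates to simulate.
#' @param params Base [dynamics_params()] supplying `beta`, `dt`, `t0`,
#'   `sigma_p` and `lambda_t`.
#' @param landscapes Named list of [drift_landscape()] objects; defaults
#'   to `continuous` (flat) and `discrete` (two-well).
#' @param delays Task delays at which accuracy is measured.
#' @param trials_per_rep Trials per simulated sequence.
#' @param n_reps Independent sequences per condition.
#' @param seed Root seed.
#' @return A tibble with one row per
#'   (landscape, sigma, beta_p, delay): `mse` (mean over reps),
#'   `mse_var` (variance over reps), `n_trials`.
#' @export
attractor_comparison <- function(sigma_levels = c(0, 0.0977),
                                 beta_p_levels = c(0, 9.9976),
                                 params = params_plastic_fit(lambda_t = 0.8),
                                 landscapes = list(
                                   continuous = drift_landscape(0),
                                   discrete = two_well_landscape()
                                 ),
                                 delays = task_delays(),
                                 trials_per_rep = 60L, n_reps = 5L, seed = 1L) {
  grid_df <- tidyr::expand_grid(
    landscape = names(landscapes),
    sigma = sigma_levels,
    beta_p = beta_p_levels
  )
  purrr::pmap_dfr(grid_df, function(landscape, sigma, beta_p) {
    p <- dynamics_params(
      beta = params$beta, sigma = sigma, dt = params$dt, t0 = params$t0,
      beta_p = beta_p, sigma_p = params$sigma_p, lambda_t = params$lambda_t,
      noise_scaling = params$noise_scaling
    )
    scape <- landscapes[[landscape]]
    reps <- purrr::map_dfr(seq_len(n_reps), function(r) {
      s <- derive_seed(seed, r, match(landscape, names(landscapes)) * 1000 +
                         round(sigma * 1e4) %% 997)
      set.seed(derive_seed(s, 0, 1))
      targets <- stats::runif(trials_per_rep, 0.1, 0.9)
      trial_delays <- delays[sample.int(length(delays), trials_per_rep,
                                        replace = TRUE)]
      sim <- simulate_trial_sequence(scape, p, targets, trial_delays, seed = s)
      sim |>
        dplyr::group_by(.data$delay_s) |>
        dplyr::summarise(
          mse = mean((.data$response - .data$target)^2),
          n = dplyr::n(), .groups = "drop"
        ) |>
        dplyr::mutate(rep = r)
    })
    reps |>
      dplyr::group_by(.data$delay_s) |>
      dplyr::summarise(
        mse_var = stats::var(.data$mse),
        n_trials = sum(.data$n),
        mse = mean(.data$mse),
        .groups = "drop"
      ) |>
      dplyr::mutate(landscape = landscape, sigma = sigma, beta_p = beta_p) |>
      dplyr::select("landscape", "sigma", "beta_p", "delay_s",
                    "mse", "mse_var", "n_trials")
  })
}
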