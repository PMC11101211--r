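#' Configuration for landscape-model fitting
#'
#' Collects every knob of the Monte-Carlo fitting procedure. Parameter
#' box constraints default to the published search ranges
#' ([param_bounds()]): drift in `[-5, 5]`, drift strength in
#' `[0.03, 0.2]`, noise strength in `[0, 0.2]`, delay term in `[1, 4]`,
#' plastic weight in `[0.1, 15]` and plastic sigma in `[0.015, 0.05]`.
#'
#' @param model `"static"` or `"plastic"` (plastic adds `beta_p`,
#'   `sigma_p`; for the static model they are pinned to 0).
#' @param n_starts Starting positions (default 50, spanning 0.1–0.9).
#' @param n_runs Monte-Carlo runs per start per cost evaluation
#'   (default 300).
#' @param dt Euler step (s).
#' @param horizon Longest task delay simulated (s).
#' @param delays Task delays the cost sums over.
#' @param fit_drift Fit the 50 drift values in phase 1 (`FALSE` freezes
#'   the landscape at its initial value, as in the parameter-recovery
#'   study).
#' @param fit_t0 Fit the delay term `t0` (`FALSE` freezes it).
#' @param encoding Also fit encoding-period `beta_enc` / `sigma_enc`.
#' @param bounds Bounds table as from [param_bounds()].
#' @param n_error_bins,n_target_bins Distribution discretization.
#' @param smoothing_width Gaussian smoothing width of the drift grid.
#' @param eps Probability floor applied to model bins before KL /
#'   likelihood.
#' @param max_evals_phase1,max_evals_phase2 Cost-evaluation budgets for
#'   the full-parameter and dynamics-only pattern-search phases.
#' @param step0,min_step Initial and terminal pattern-search mesh size as
#'   fractions of each parameter's box width.
#' @param seed Root seed; the same noise substreams are reused for every
#'   cost evaluation (common random numbers), which makes the search
#'   surface deterministic.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(model = c("static", "plastic"),
                       n_starts = 50L, n_runs = 300L, dt = 0.1, horizon = 20,
                       delays = task_delays(),
                       fit_drift = TRUE, fit_t0 = TRUE, encoding = FALSE,
                       bounds = param_bounds(),
                       n_error_bins = 50L, n_target_bins = 50L,
                       smoothing_width = 0.02,
                       eps = 1e-6,
                       max_evals_phase1 = 2000L, max_evals_phase2 = 500L,
                       step0 = 0.25, min_step = 1e-3, seed = 1L) {
  model <- match.arg(model)
  stopifnot(n_starts >= 1L, n_runs >= 1L, dt > 0)
  structure(
    list(model = model, n_starts = n_starts, n_runs = n_runs, dt = dt,
         horizon = horizon, delays = sort(delays),
         fit_drift = fit_drift, fit_t0 = fit_t0, encoding = encoding,
         bounds = bounds, n_error_bins = n_error_bins,
         n_target_bins = n_target_bins, smoothing_width = smoothing_width,
         eps = eps, max_evals_phase1 = max_evals_phase1,
         max_evals_phase2 = max_evals_phase2,
         step0 = step0, min_step = min_step, seed = seed),
    class = "fit_config"
  )
}

#' Model-side response distributions
#'
#' Simulates the model from `n_starts` starting positions spanning
#' 0.1–0.9 with `n_runs` Monte-Carlo runs each, records positions at
#' internal times `t0 + delay` for every task delay, and reduces the
#' errors to a [response_distribution_set()] with the same kernel density
#' estimate as the data side, plus the length-3 moving-mean smoothing
#' that damps Monte-Carlo jitter.
#'
#' @param landscape A [drift_landscape()].
#' @param params A [dynamics_params()].
#' @param delays Task delays (sorted).
#' @param n_starts,n_runs Monte-Carlo design.
#' @param seed Seed (ignored when `noise` is supplied).
#' @param noise Optional pre-drawn standard-normal matrix for common
#'   random numbers.
#' @param smooth_stencil Apply the stencil-3 smoothing (default TRUE).
#' @param bw Optional fixed KDE bandwidth.
#' @return A [response_distribution_set()].
#' @export
simulate_model_distributions <- function(landscape, params,
                                         delays = task_delays(),
                                         n_starts = 50L, n_runs = 300L,
                                         seed = 1L, noise = NULL,
                                         smooth_stencil = TRUE, bw = NULL) {
  delays <- sort(delays)
  starts <- seq(0.1, 0.9, length.out = n_starts)
  record_times <- params$t0 + delays
  pos <- simulate_landscape(landscape, params, starts, record_times,
                            n_runs = n_runs, seed = seed, noise = noise)
  n_error_bins <- 50L
  error_range <- c(-0.25, 0.25)
  w <- diff(error_range) / n_error_bins
  error_centers <- seq(error_range[1] + w / 2, error_range[2] - w / 2,
                       length.out = n_error_bins)
  prob <- array(0, dim = c(n_error_bins, n_starts, length(delays)))
  for (di in seq_along(delays)) {
    for (si in seq_len(n_starts)) {
      e <- pos[si, , di] - starts[si]
      p <- kde_error_vector(e, error_centers, bw = bw)
      if (smooth_stencil) p <- stencil3(p)
      prob[, si, di] <- p
    }
  }
  response_distribution_set(prob, error_centers, starts, delays)
}

#' Kullback–Leibler cost between data and model distribution sets
#'
#' Sum over all (target bin, delay) cells of `KL(data || model)` in nats,
#' with model bins floored at `eps` and renormalized so empty Monte-Carlo
#' bins cannot produce infinite cost. Data is the reference measure:
#' the model is penalized wherever it misses observed mass.
#'
#' @param data_set,model_set [response_distribution_set()] objects of
#'   matching shape.
#' @param eps Probability floor for model bins.
#' @return Non-negative cost in nats.
#' @export
kl_cost <- function(data_set, model_set, eps = 1e-6) {
  p <- unclass(data_set)
  q <- unclass(model_set)
  if (!identical(dim(p), dim(q))) stop("shapes do not match", call. = FALSE)
  q <- pmax(q, eps)
  # renormalize each cell vector after flooring
  sums <- apply(q, c(2, 3), sum)
  q <- sweep(q, c(2, 3), sums, "/")
  ok <- p > 0
  sum(p[ok] * log(p[ok] / q[ok]))
}

# Cyclic coordinate pattern search under box constraints. Polls +/- one
# mesh step per coordinate (opportunistic: accepts the first improving
# move); after a full unsuccessful cycle the mesh contracts by half.
# The objective must be deterministic for the contraction logic to mean
# anything -- cost evaluations therefore share common random numbers.
pattern_search <- function(par, fn, lower, upper,
                           step0 = 0.25, min_step = 1e-3, max_evals = 1000L,
                           trace = FALSE) {
  n <- length(par)
  scale <- upper - lower
  par <- pmin(pmax(par, lower), upper)
  f <- fn(par)
  evals <- 1L
  step <- step0
  history <- c(f)
  while (step >= min_step && evals < max_evals) {
    improved <- FALSE
    for (i in seq_len(n)) {
      for (sgn in c(1, -1)) {
        if (evals >= max_evals) break
        cand <- par
        cand[i] <- min(max(par[i] + sgn * step * scale[i], lower[i]), upper[i])
        if (cand[i] == par[i]) next
        fc <- fn(cand)
        evals <- evals + 1L
        if (fc < f) {
          par <- cand
          f <- fc
          improved <- TRUE
          if (trace) history <- c(history, f)
          break
        }
      }
    }
    if (!improved) step <- step / 2
  }
  list(par = par, value = f, evals = evals, step = step, trace = history)
}

# Pack/unpack the fitting parameter vector given a config.
param_layout <- function(config) {
  b <- config$bounds
  row <- function(nm) b[b$name == nm, ]
  names <- character(0)
  lower <- upper <- init <- numeric(0)
  if (config$fit_drift) {
    nd <- 50L
    names <- c(names, rep("drift", nd))
    lower <- c(lower, rep(row("drift")$lower, nd))
    upper <- c(upper, rep(row("drift")$upper, nd))
    init <- c(init, rep(0, nd))
  }
  for (nm in c("beta", "sigma", if (config$fit_t0) "t0",
               if (config$model == "plastic") c("beta_p", "sigma_p"))) {
    r <- row(nm)
    names <- c(names, nm)
    lower <- c(lower, r$lower)
    upper <- c(upper, r$upper)
    init <- c(init, (r$lower + r$upper) / 2)
  }
  list(names = names, lower = lower, upper = upper, init = init)
}

unpack_params <- function(par, names, config, base_landscape, base_params) {
  par <- unname(par)
  drift <- base_landscape$drift
  get1 <- function(nm, default) {
    i <- which(names == nm)
    if (length(i)) par[i] else default
  }
  if (config$fit_drift) drift <- par[names == "drift"]
  landscape <- drift_landscape(drift, smoothing_width = config$smoothing_width)
  params <- dynamics_params(
    beta = get1("beta", base_params$beta),
    sigma = get1("sigma", base_params$sigma),
    dt = config$dt,
    t0 = get1("t0", base_params$t0),
    beta_p = if (config$model == "plastic") get1("beta_p", base_params$beta_p) else 0,
    sigma_p = if (config$model == "plastic") get1("sigma_p", base_params$sigma_p)
      else base_params$sigma_p,
    lambda_t = base_params$lambda_t,
    noise_scaling = base_params$noise_scaling
  )
  list(landscape = landscape, params = params)
}

#' Fit a landscape model to a data distribution set
#'
#' Two-phase box-constrained pattern search minimizing [kl_cost()]
#' between the data distributions and the Monte-Carlo model
#' distributions. Phase 1 searches the full parameter set (the gridded
#' drift values plus the dynamics parameters); phase 2 re-polls only the
#' dynamics parameters with the landscape frozen. Every cost evaluation
#' reuses the same per-(start, run) noise substreams (common random
#' numbers), so the objective is a deterministic function of the
#' parameters given the config seed.
#'
#' @param data_set Data-side [response_distribution_set()] covering the
#'   config delays.
#' @param config A [fit_config()].
#' @param init_landscape Optional starting landscape (required when
#'   `fit_drift = FALSE`; defaults to a flat zero-drift profile).
#' @param init_params Optional starting [dynamics_params()]; defaults to
#'   bound midpoints.
#' @return Object of class `landscape_fit`: `landscape`, `params`,
#'   `cost`, `k` (free-parameter count), `trace`, `n_evals`,
#'   `converged`, `config`.
#' @export
fit_landscape_model <- function(data_set, config = fit_config(),
                                init_landscape = NULL, init_params = NULL) {
  if (!setequal(attr(data_set, "delays"), config$delays)) {
    stop("data distribution set does not cover the config delays", call. = FALSE)
  }
  base_landscape <- init_landscape %||%
    drift_landscape(0, n_grid = 50L, smoothing_width = config$smoothing_width)
  base_params <- init_params %||% dynamics_params(dt = config$dt)

  layout <- param_layout(config)
  par0 <- layout$init
  if (!is.null(init_params)) {
    for (nm in c("beta", "sigma", "t0", "beta_p", "sigma_p")) {
      i <- which(layout$names == nm)
      if (length(i)) par0[i] <- init_params[[nm]]
    }
  }
  if (config$fit_drift && !is.null(init_landscape)) {
    par0[layout$names == "drift"] <- init_landscape$drift
  }
  par0 <- pmin(pmax(par0, layout$lower), layout$upper)

  # common random numbers sized for the largest admissible t0
  t0_max <- max(config$bounds[config$bounds$name == "t0", ]$upper,
                base_params$t0)
  n_steps_max <- as.integer(round((config$horizon + t0_max) / config$dt)) + 1L
  z <- noise_matrix(config$seed, config$n_starts * config$n_runs, n_steps_max)

  cost_fn <- function(par) {
    m <- unpack_params(par, layout$names, config, base_landscape, base_params)
    model_set <- simulate_model_distributions(
      m$landscape, m$params, delays = config$delays,
      n_starts = config$n_starts, n_runs = config$n_runs, noise = z
    )
    kl_cost(data_set, model_set, eps = config$eps)
  }

  ps1 <- pattern_search(par0, cost_fn, layout$lower, layout$upper,
                        step0 = config$step0, min_step = config$min_step,
                        max_evals = config$max_evals_phase1, trace = TRUE)

  # phase 2: dynamics only, landscape frozen at the phase-1 result
  m1 <- unpack_params(ps1$par, layout$names, config, base_landscape, base_params)
  config2 <- config
  config2$fit_drift <- FALSE
  layout2 <- param_layout(config2)
  par2 <- vapply(layout2$names, function(nm) m1$params[[nm]], numeric(1))
  par2 <- pmin(pmax(par2, layout2$lower), layout2$upper)
  cost_fn2 <- function(par) {
    m <- unpack_params(par, layout2$names, config2, m1$landscape, m1$params)
    model_set <- simulate_model_distributions(
      m$landscape, m$params, delays = config$delays,
      n_starts = config$n_starts, n_runs = config$n_runs, noise = z
    )
    kl_cost(data_set, model_set, eps = config$eps)
  }
  ps2 <- pattern_search(par2, cost_fn2, layout2$lower, layout2$upper,
                        step0 = config$step0 / 2, min_step = config$min_step,
                        max_evals = config$max_evals_phase2, trace = TRUE)

  use2 <- ps2$value <= ps1$value
  final <- if (use2) {
    unpack_params(ps2$par, layout2$names, config2, m1$landscape, m1$params)
  } else m1
  cost <- min(ps1$value, ps2$value)
  k <- (if (config$fit_drift) 50L else 0L) + 2L + as.integer(config$fit_t0) +
    (if (config$model == "plastic") 2L else 0L) +
    (if (config$encoding) 2L else 0L)

  structure(
    list(
      landscape = final$landscape, params = final$params,
      cost = cost, k = k,
      trace = c(ps1$trace, ps2$trace),
      n_evals = ps1$evals + ps2$evals,
      converged = cost < ps1$trace[1],
      config = config
    ),
    class = "landscape_fit"
  )
}

#' @export
print.landscape_fit <- function(x, ...) {
  cat(sprintf(
    "<landscape_fit> %s model: KL cost %.4f after %d evaluations (k = %d)%s\n",
    x$config$model, x$cost, x$n_evals, x$k,
    if (!x$converged) " [no improvement over initialization]" else ""
  ))
  cat(sprintf("  beta %.4g  sigma %.4g  t0 %.4g", x$params$beta,
              x$params$sigma, x$params$t0))
  if (x$config$model == "plastic") {
    cat(sprintf("  beta_p %.4g  sigma_p %.4g", x$params$beta_p, x$params$sigma_p))
  }
  cat("\n")
  invisible(x)
}

#' Bias-matching meta cost
#'
#' The cost used when fitting a model to the bias summary statistics
#' rather than the full response distributions: squared bias error per
#' delay plus squared time-constant error, each normalized by the
#' observed value,
#' `C = sum_t (Bm - Bd)^2 / Bd + (tau_m - tau_d)^2 / tau_d`.
#' Zero observed values are floored at `eps` to guard the normalization.
#'
#' @param bias_model,bias_data Overall bias per delay (same order).
#' @param tau_model,tau_data Bias-curve time constants.
#' @param eps Normalization floor.
#' @return Non-negative cost.
#' @export
bias_meta_cost <- function(bias_model, bias_data, tau_model, tau_data,
                           eps = 1e-6) {
  if (length(bias_model) != length(bias_data)) {
    stop("bias vectors must have the same length", call. = FALSE)
  }
  sum((bias_model - bias_data)^2 / pmax(bias_data, eps)) +
    (tau_model - tau_data)^2 / max(tau_data, eps)
}

#' Fit the static model to the bias curve only
#'
#' Replaces the distribution-matching cost with a meta cost built from
#' the bias summary statistics: the squared error between model and data
#' overall bias at every delay plus the squared error between the model
#' and data bias time constants, each normalized by the observed value,
#' `C = sum_t (Bm - Bd)^2 / Bd + (tau_m - tau_d)^2 / tau_d`.
#' The model bias at a delay is the maximum absolute mean error across
#' starting positions; the time constants come from [fit_bias_curve()].
#'
#' @param bias_data Tibble with `delay_s` and `bias` (data overall bias
#'   per delay, e.g. from [bias_by_delay()]).
#' @param tau_data Fitted data time constant (`1 / lambda` is not used;
#'   the rate's reciprocal convention follows the saturation fit: pass
#'   the fitted `lambda`).
#' @param config A [fit_config()] (`model` is forced to static).
#' @param init_landscape,init_params As in [fit_landscape_model()].
#' @param eps Floor protecting the normalization when a data bias is 0.
#' @return A `landscape_fit` whose `cost` is the meta cost.
#' @export
fit_bias_only <- function(bias_data, tau_data, config = fit_config(),
                          init_landscape = NULL, init_params = NULL,
                          eps = 1e-6) {
  config$model <- "static"
  base_landscape <- init_landscape %||%
    drift_landscape(0, n_grid = 50L, smoothing_width = config$smoothing_width)
  base_params <- init_params %||% dynamics_params(dt = config$dt)
  layout <- param_layout(config)
  par0 <- layout$init
  if (config$fit_drift && !is.null(init_landscape)) {
    par0[layout$names == "drift"] <- init_landscape$drift
  }
  par0 <- pmin(pmax(par0, layout$lower), layout$upper)
  delays <- config$delays
  bias_d <- bias_data$bias[match(delays, bias_data$delay_s)]

  t0_max <- max(config$bounds[config$bounds$name == "t0", ]$upper, base_params$t0)
  n_steps_max <- as.integer(round((config$horizon + t0_max) / config$dt)) + 1L
  z <- noise_matrix(config$seed, config$n_starts * config$n_runs, n_steps_max)
  starts <- seq(0.1, 0.9, length.out = config$n_starts)

  cost_fn <- function(par) {
    m <- unpack_params(par, layout$names, config, base_landscape, base_params)
    pos <- simulate_landscape(m$landscape, m$params, starts,
                              m$params$t0 + delays,
                              n_runs = config$n_runs, noise = z)
    bias_m <- vapply(seq_along(delays), function(di) {
      pm <- matrix(pos[, , di], nrow = length(starts))
      max(abs(rowMeans(pm - starts)))
    }, numeric(1))
    tau_m <- tryCatch(
      fit_bias_curve(delays, bias_m, n_boot = 0)$lambda,
      error = function(e) NA_real_
    )
    if (is.finite(tau_m)) {
      bias_meta_cost(bias_m, bias_d, tau_m, tau_data, eps = eps)
    } else {
      sum((bias_m - bias_d)^2 / pmax(bias_d, eps)) + 10 * sum(bias_d^2)
    }
  }

  ps <- pattern_search(par0, cost_fn, layout$lower, layout$upper,
                       step0 = config$step0, min_step = config$min_step,
                       max_evals = config$max_evals_phase1, trace = TRUE)
  final <- unpack_params(ps$par, layout$names, config, base_landscape, base_params)
  k <- (if (config$fit_drift) 50L else 0L) + 2L + as.integer(config$fit_t0)
  structure(
    list(landscape = final$landscape, params = final$params,
         cost = ps$value, k = k, trace = ps$trace, n_evals = ps$evals,
         converged = ps$value < ps$trace[1], config = config,
         cost_type = "bias_meta"),
    class = "landscape_fit"
  )
}
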