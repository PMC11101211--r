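#' Log-likelihood of trials under a model distribution set
#'
#' Each trial is mapped to its nearest target bin, its delay and its
#' error bin, and contributes the log of the model's (floored,
#' renormalized) bin probability. Errors outside the `[-0.25, 0.25]`
#' support are clipped to the edge bin and counted.
#'
#' @param model_set A [response_distribution_set()].
#' @param trials Trial table; every `delay_s` must be one of the set's
#'   delays.
#' @param eps Probability floor.
#' @return Log-likelihood (nats) with attributes `n` (trials used) and
#'   `n_clipped`.
#' @export
log_likelihood <- function(model_set, trials, eps = 1e-6) {
  delays <- attr(model_set, "delays")
  targets <- attr(model_set, "target_centers")
  errors <- attr(model_set, "error_centers")
  trials <- trials[!is.na(trials$response), , drop = FALSE]
  if (!all(trials$delay_s %in% delays)) {
    stop("trials contain delays absent from the model distribution set",
         call. = FALSE)
  }
  q <- pmax(unclass(model_set), eps)
  sums <- apply(q, c(2, 3), sum)
  q <- sweep(q, c(2, 3), sums, "/")

  t_spacing <- targets[2] - targets[1]
  e_spacing <- errors[2] - errors[1]
  ti <- pmin(pmax(round((trials$target - targets[1]) / t_spacing) + 1L, 1L),
             length(targets))
  di <- match(trials$delay_s, delays)
  err <- trials$response - trials$target
  n_clipped <- sum(err < errors[1] - e_spacing / 2 | err > errors[length(errors)] + e_spacing / 2)
  ei <- pmin(pmax(round((err - errors[1]) / e_spacing) + 1L, 1L), length(errors))
  ll <- sum(log(q[cbind(ei, ti, di)]))
  attr(ll, "n") <- nrow(trials)
  attr(ll, "n_clipped") <- n_clipped
  ll
}

#' Akaike and Bayesian information criteria
#'
#' `AIC = 2k - 2 loglik` and `BIC = k ln(n) - 2 loglik`.
#'
#' @param loglik Log-likelihood.
#' @param k Number of free parameters.
#' @param n Number of observations.
#' @return Named list with `aic` and `bic`.
#' @export
aic_bic <- function(loglik, k, n) {
  stopifnot(n >= 1, k >= 0)
  loglik <- as.numeric(loglik)
  list(aic = 2 * k - 2 * loglik, bic = k * log(n) - 2 * loglik)
}

# Resolve a model argument for compare_models(): either a landscape_fit
# (simulated to a distribution set) or a list(model_set =, k =).
resolve_model <- function(m, delays, n_starts, n_runs, seed) {
  if (inherits(m, "landscape_fit")) {
    list(
      model_set = simulate_model_distributions(
        m$landscape, m$params, delays = delays,
        n_starts = n_starts, n_runs = n_runs, seed = seed
      ),
      k = m$k
    )
  } else {
    stopifnot(is.list(m), !is.null(m$model_set), !is.null(m$k))
    m
  }
}

#' Bootstrap model comparison by AIC / BIC
#'
#' Bootstraps the trials, recomputes the log-likelihood of both (fixed,
#' already-fitted) models on each resample, and reports the empirical
#' p-value: the fraction of resamples on which the information-criterion
#' difference has the sign opposite to the point estimate, floored at
#' `1 / n_boot`.
#'
#' @param model_a,model_b `landscape_fit` objects, or lists with
#'   `model_set` (a [response_distribution_set()]) and `k`.
#' @param trials Trial table both models are evaluated on.
#' @param n_boot Bootstrap repetitions (default 1000).
#' @param seed Seed for resampling (and for simulating model
#'   distributions when fits are passed).
#' @param n_starts,n_runs Monte-Carlo design used when a `landscape_fit`
#'   must be simulated to a distribution set.
#' @param eps Probability floor for the likelihood.
#' @return Object of class `model_comparison`: tibble `summary` (per
#'   model: loglik, k, AIC, BIC), `delta` (point-estimate differences
#'   A - B), bootstrap distributions, `p_aic`, `p_bic` and p-value
#'   labels honouring the `1 / n_boot` floor.
#' @export
compare_models <- function(model_a, model_b, trials, n_boot = 1000L, seed = 1L,
                           n_starts = 50L, n_runs = 300L, eps = 1e-6) {
  delays <- sort(unique(trials$delay_s))
  a <- resolve_model(model_a, delays, n_starts, n_runs, derive_seed(seed, 1))
  b <- resolve_model(model_b, delays, n_starts, n_runs, derive_seed(seed, 2))
  n <- nrow(trials)

  ic_of <- function(df) {
    lla <- log_likelihood(a$model_set, df, eps = eps)
    llb <- log_likelihood(b$model_set, df, eps = eps)
    nn <- nrow(df)
    ica <- aic_bic(lla, a$k, nn)
    icb <- aic_bic(llb, b$k, nn)
    c(aic_a = ica$aic, bic_a = ica$bic, aic_b = icb$aic, bic_b = icb$bic,
      ll_a = as.numeric(lla), ll_b = as.numeric(llb))
  }

  point <- ic_of(trials)
  set.seed(seed)
  boot <- t(vapply(seq_len(n_boot), function(i) {
    ic_of(trials[sample.int(n, n, replace = TRUE), , drop = FALSE])
  }, numeric(6)))

  d_aic <- point[["aic_a"]] - point[["aic_b"]]
  d_bic <- point[["bic_a"]] - point[["bic_b"]]
  boot_d_aic <- boot[, "aic_a"] - boot[, "aic_b"]
  boot_d_bic <- boot[, "bic_a"] - boot[, "bic_b"]
  p_of <- function(delta, boot_delta) {
    # ties count half, so two literally identical models score p = 0.5
    contrary <- if (delta < 0) {
      mean(boot_delta > 0) + 0.5 * mean(boot_delta == 0)
    } else {
      mean(boot_delta < 0) + 0.5 * mean(boot_delta == 0)
    }
    max(contrary, 1 / n_boot)
  }
  p_aic <- p_of(d_aic, boot_d_aic)
  p_bic <- p_of(d_bic, boot_d_bic)

  structure(
    list(
      summary = tibble::tibble(
        model = c("A", "B"),
        loglik = c(point[["ll_a"]], point[["ll_b"]]),
        k = c(a$k, b$k),
        aic = c(point[["aic_a"]], point[["aic_b"]]),
        bic = c(point[["bic_a"]], point[["bic_b"]])
      ),
      delta = c(aic = d_aic, bic = d_bic),
      boot_delta_aic = boot_d_aic,
      boot_delta_bic = boot_d_bic,
      p_aic = p_aic, p_bic = p_bic,
      p_aic_label = if (p_aic <= 1 / n_boot) sprintf("<%g", 1 / n_boot)
        else sprintf("%g", p_aic),
      p_bic_label = if (p_bic <= 1 / n_boot) sprintf("<%g", 1 / n_boot)
        else sprintf("%g", p_bic),
      n = n, n_boot = n_boot
    ),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>\n")
  print(x$summary)
  cat(sprintf("  delta AIC (A - B) %.2f, p %s; delta BIC %.2f, p %s\n",
              x$delta[["aic"]], x$p_aic_label, x$delta[["bic"]], x$p_bic_label))
  invisible(x)
}

#' Robustness scan of the plasticity parameters
#'
#' Holds a fitted parameter set fixed and varies the plastic weight
#' (`beta_p`) and plastic sigma (`sigma_p`) one at a time across their
#' full search ranges, re-evaluating the KL fitting loss several times
#' per value with fresh Monte-Carlo noise, and reporting the mean and
#' standard deviation of the loss. The fitted value itself is included
#' in each grid.
#'
#' @param fit A `landscape_fit` (plastic model).
#' @param data_set Data-side [response_distribution_set()].
#' @param parameters Which parameters to scan.
#' @param n_values Grid size per parameter.
#' @param n_reps Loss evaluations per value (default 5).
#' @param n_starts,n_runs Monte-Carlo design per evaluation.
#' @param seed Root seed.
#' @return Tibble with `parameter`, `value`, `mean_loss`, `sd_loss`,
#'   `is_fitted`.
#' @export
robustness_scan <- function(fit, data_set,
                            parameters = c("beta_p", "sigma_p"),
                            n_values = 10L, n_reps = 5L,
                            n_starts = 50L, n_runs = 300L, seed = 1L) {
  bounds <- fit$config$bounds
  delays <- attr(data_set, "delays")
  purrr::map_dfr(parameters, function(pname) {
    r <- bounds[bounds$name == pname, ]
    fitted_value <- fit$params[[pname]]
    grid <- sort(unique(c(seq(r$lower, r$upper, length.out = n_values),
                          fitted_value)))
    purrr::map_dfr(seq_along(grid), function(gi) {
      p <- fit$params
      p[[pname]] <- grid[gi]
      p <- dynamics_params(beta = p$beta, sigma = p$sigma, dt = p$dt,
                           t0 = p$t0, beta_p = p$beta_p, sigma_p = p$sigma_p,
                           lambda_t = p$lambda_t,
                           noise_scaling = p$noise_scaling)
      losses <- vapply(seq_len(n_reps), function(rep) {
        ms <- simulate_model_distributions(
          fit$landscape, p, delays = delays,
          n_starts = n_starts, n_runs = n_runs,
          seed = derive_seed(seed, gi, rep + 100 * match(pname, parameters))
        )
        kl_cost(data_set, ms, eps = fit$config$eps)
      }, numeric(1))
      tibble::tibble(
        parameter = pname, value = grid[gi],
        mean_loss = mean(losses), sd_loss = stats::sd(losses),
        is_fitted = grid[gi] == fitted_value
      )
    })
  })
}
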