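#' Dynamics parameters for the landscape models
#'
#' Bundles every parameter that, together with a [drift_landscape()],
#' fully defines a model of the memory trace:
#'
#' * `beta` — drift strength, the dimensionless multiplier on `G(x)`.
#' * `sigma` — noise strength, the standard deviation of the zero-mean
#'   Gaussian increment drawn each step (see Details for the time
#'   scaling).
#' * `dt` — Euler time step in seconds (0.1 throughout the studies).
#' * `t0` — encoding delay in seconds: a task delay `d` corresponds to
#'   internal simulation time `t0 + d`.
#' * `beta_p` — plasticity growth rate. Each step, a derivative-of-Gaussian
#'   perturbation centered at the trace's current position is added to the
#'   drift profile, scaled by `beta_p * dt`; this carves a local depression
#'   into the energy landscape that impedes descent into the attractor.
#'   `beta_p = 0` recovers the static model exactly.
#' * `sigma_p` — width of the plastic kernel in line units.
#' * `lambda_t` — inter-trial decay in `[0, 1]`: at each trial boundary the
#'   drift profile is reset to
#'   `lambda_t * static + (1 - lambda_t) * final`, so `1` is a full reset
#'   and values below 1 let plasticity carry over and produce proactive
#'   interference.
#' * `beta_enc`, `sigma_enc` — optional encoding-period drift/noise that
#'   govern the first `t0` seconds only (both `NA` by default, meaning the
#'   delay-period values apply throughout).
#'
#' @details
#' The per-step update is `x <- x + (beta * G(x) + eps) * dt` with
#' `eps ~ Normal(0, sigma^2)` drawn each step, i.e. the noise increment is
#' scaled by `dt` (not `sqrt(dt)`). This literal discretization is the
#' scaling under which the fitted noise-strength values are meaningful;
#' set `noise_scaling = "sqrt_dt"` for the standard Euler–Maruyama variant
#' when comparing discretizations.
#'
#' @param beta,sigma,dt,t0,beta_p,sigma_p,lambda_t,beta_enc,sigma_enc See
#'   description.
#' @param noise_scaling `"dt"` (default, literal) or `"sqrt_dt"`.
#' @return An object of class `dynamics_params`.
#' @examples
#' dynamics_params(beta = 0.05, sigma = 0.08)
#' @export
dynamics_params <- function(beta = 0.1, sigma = 0.1, dt = 0.1, t0 = 1.5,
                            beta_p = 0, sigma_p = 0.02, lambda_t = 1,
                            beta_enc = NA_real_, sigma_enc = NA_real_,
                            noise_scaling = c("dt", "sqrt_dt")) {
  noise_scaling <- match.arg(noise_scaling)
  for (nm in c("beta", "sigma", "dt", "t0", "beta_p", "sigma_p", "lambda_t")) {
    stopifnot_scalar(get(nm), nm)
  }
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (sigma < 0) stop("`sigma` must be non-negative", call. = FALSE)
  if (t0 < 0) stop("`t0` must be non-negative", call. = FALSE)
  if (beta_p < 0) stop("`beta_p` must be non-negative", call. = FALSE)
  if (beta_p > 0 && sigma_p <= 0) {
    stop("`sigma_p` must be positive when `beta_p` > 0", call. = FALSE)
  }
  if (lambda_t < 0 || lambda_t > 1) stop("`lambda_t` must lie in [0, 1]", call. = FALSE)
  structure(
    list(
      beta = beta, sigma = sigma, dt = dt, t0 = t0,
      beta_p = beta_p, sigma_p = sigma_p, lambda_t = lambda_t,
      beta_enc = beta_enc, sigma_enc = sigma_enc,
      noise_scaling = noise_scaling
    ),
    class = "dynamics_params"
  )
}

#' @export
print.dynamics_params <- function(x, ...) {
  cat("<dynamics_params>\n")
  cat(sprintf(
    "  beta %g  sigma %g  dt %g  t0 %g\n  beta_p %g  sigma_p %g  lambda_t %g\n",
    x$beta, x$sigma, x$dt, x$t0, x$beta_p, x$sigma_p, x$lambda_t
  ))
  if (is.finite(x$beta_enc) || is.finite(x$sigma_enc)) {
    cat(sprintf("  encoding: beta_enc %g  sigma_enc %g\n", x$beta_enc, x$sigma_enc))
  }
  invisible(x)
}

#' Published parameter sets and fitting bounds
#'
#' `params_static_fit()` and `params_plastic_fit()` return the parameter
#' values of the static and plastic landscape models fitted to the pooled
#' behavioral data; `params_static_meta()` is the static model fitted to
#' the bias curve only. `param_bounds()` returns the box constraints used
#' during fitting.
#'
#' @param ... Overrides passed to [dynamics_params()] (e.g. `lambda_t`).
#' @return A [dynamics_params()], or for `param_bounds()` a tibble with
#'   columns `name`, `lower`, `upper`.
#' @export
params_static_fit <- function(...) {
  args <- utils::modifyList(
    list(beta = 0.0481, sigma = 0.0821, t0 = 1.22, beta_p = 0),
    list(...)
  )
  do.call(dynamics_params, args)
}

#' @rdname params_static_fit
#' @export
params_static_meta <- function(...) {
  args <- utils::modifyList(
    list(beta = 0.0998, sigma = 0.0759, t0 = 3.50, beta_p = 0),
    list(...)
  )
  do.call(dynamics_params, args)
}

#' @rdname params_static_fit
#' @export
params_plastic_fit <- function(...) {
  args <- utils::modifyList(
    list(beta = 0.0794, sigma = 0.0977, t0 = 2.4843,
         beta_p = 9.9976, sigma_p = 0.0218),
    list(...)
  )
  do.call(dynamics_params, args)
}

#' @rdname params_static_fit
#' @export
param_bounds <- function() {
  tibble::tibble(
    name = c("drift", "beta", "sigma", "t0", "beta_p", "sigma_p"),
    label = c("Drift", "Drift strength", "Noise strength", "Delay term",
              "Plastic weight", "Plastic sigma"),
    lower = c(-5, 0.03, 0, 1.0, 0.1, 0.015),
    upper = c(5, 0.2, 0.2, 4, 15, 0.05)
  )
}

#' Read / write dynamics parameters as a key-value config
#'
#' Flat `key = value` text with the machine parameter names (`beta`,
#' `sigma`, `dt`, `t0`, `beta_p`, `sigma_p`, `lambda_t`, `beta_enc`,
#' `sigma_enc`). Round-trips at full double precision.
#'
#' @param params A [dynamics_params()].
#' @param path File path.
#' @return `write_params()` returns `path` invisibly; `read_params()` a
#'   [dynamics_params()].
#' @export
write_params <- function(params, path) {
  keys <- c("beta", "sigma", "dt", "t0", "beta_p", "sigma_p", "lambda_t",
            "beta_enc", "sigma_enc")
  vals <- vapply(keys, function(k) sprintf("%.17g", params[[k]]), character(1))
  writeLines(c(paste(keys, "=", vals),
               paste("noise_scaling", "=", params$noise_scaling)), path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  kv <- strsplit(lines, "\\s*[=:]\\s*")
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, `[`, character(1), 2)
  names(vals) <- trimws(keys)
  num <- function(k, default) {
    if (!k %in% names(vals)) return(default)
    v <- trimws(vals[[k]])
    if (v %in% c("NA", "nan", "NaN")) NA_real_ else as.numeric(v)
  }
  dynamics_params(
    beta = num("beta", 0.1), sigma = num("sigma", 0.1),
    dt = num("dt", 0.1), t0 = num("t0", 1.5),
    beta_p = num("beta_p", 0), sigma_p = num("sigma_p", 0.02),
    lambda_t = num("lambda_t", 1),
    beta_enc = num("beta_enc", NA_real_), sigma_enc = num("sigma_enc", NA_real_),
    noise_scaling = if ("noise_scaling" %in% names(vals))
      trimws(vals[["noise_scaling"]]) else "dt"
  )
}
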