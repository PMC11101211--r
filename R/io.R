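#' Read / write a trial table as CSV
#'
#' Fixed header `participant,order,target,response,delay_s,skipped`
#' (extra columns round-trip untouched). Positions are normalized to
#' `[0, 1]`; if `line_length_px` is given, pixel-coordinate targets and
#' responses are divided by it on read. Values round-trip at full double
#' precision.
#'
#' @param path File path.
#' @param trials Trial table tibble.
#' @param line_length_px Optional pixel length of the response line for
#'   normalizing pixel-coordinate input.
#' @return `read_trials_csv()` returns a tibble; `write_trials_csv()`
#'   returns `path` invisibly.
#' @export
read_trials_csv <- function(path, line_length_px = NULL) {
  trials <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("participant", "order", "target", "response", "delay_s")
  missing <- setdiff(required, names(trials))
  if (length(missing)) {
    stop(sprintf("missing required column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  if (!"skipped" %in% names(trials)) trials$skipped <- FALSE
  if (!is.null(line_length_px)) {
    trials$target <- trials$target / line_length_px
    trials$response <- trials$response / line_length_px
  }
  odd <- setdiff(unique(trials$delay_s), task_delays())
  if (length(odd)) {
    warning(sprintf("delays outside the task set kept as-is: %s",
                    paste(odd, collapse = ", ")))
  }
  trials
}

#' @rdname read_trials_csv
#' @export
write_trials_csv <- function(trials, path) {
  readr::write_csv(trials, path)
  invisible(path)
}

# Field-name variants accepted in deposited participant JSON blocks.
json_alias_table <- function() {
  list(
    target = c("target", "Target", "target_position", "targetPosition",
               "targetValue", "stimulus", "stim_pos"),
    response = c("response", "Response", "response_position",
                 "responsePosition", "responseValue", "resp", "click_position"),
    delay_s = c("delay_s", "delay", "Delay", "delay_time", "delayTime",
                "delay_seconds"),
    order = c("order", "trial", "trial_index", "trialNumber", "trial_number"),
    skipped = c("skipped", "skip", "was_skipped", "Skipped")
  )
}

pick_alias <- function(df, field, aliases, file) {
  hit <- intersect(aliases, names(df))
  if (!length(hit)) {
    if (field %in% c("order", "skipped")) return(NULL)
    stop(sprintf("file '%s': missing required field '%s' (accepted names: %s)",
                 file, field, paste(aliases, collapse = ", ")), call. = FALSE)
  }
  df[[hit[1]]]
}

#' Read a participant-folder JSON layout into a trial table
#'
#' Reads the deposited-data layout: one directory per participant, each
#' containing one JSON file per set of trial blocks. Field names are
#' mapped through an alias table (e.g. `target` / `targetPosition` /
#' `stimulus`); unknown fields are preserved in the `extra_fields`
#' attribute. Trials are ordered by file (natural sort) and then by any
#' per-file trial index, giving a stable within-participant order.
#'
#' @param root Directory whose sub-directories are participants.
#' @param line_length_px Optional pixel normalization as in
#'   [read_trials_csv()].
#' @return A trial table tibble (empty, with a warning, if no JSON files
#'   are found).
#' @export
read_participant_json <- function(root, line_length_px = NULL) {
  if (!dir.exists(root)) stop(sprintf("directory '%s' does not exist", root),
                              call. = FALSE)
  dirs <- list.dirs(root, recursive = FALSE)
  aliases <- json_alias_table()
  extra <- list()
  out <- purrr::map_dfr(dirs, function(d) {
    files <- sort(list.files(d, pattern = "\\.json$", full.names = TRUE))
    pid <- basename(d)
    rows <- purrr::map_dfr(files, function(f) {
      parsed <- tryCatch(jsonlite::fromJSON(f),
                         error = function(e) {
                           stop(sprintf("could not parse '%s': %s", f,
                                        conditionMessage(e)), call. = FALSE)
                         })
      df <- if (is.data.frame(parsed)) parsed else
        if (is.list(parsed) && !is.null(parsed$trials)) as.data.frame(parsed$trials)
        else as.data.frame(parsed)
      known <- unlist(aliases, use.names = FALSE)
      unknown <- setdiff(names(df), known)
      if (length(unknown)) {
        extra[[f]] <<- df[, unknown, drop = FALSE]
      }
      tibble::tibble(
        target = as.numeric(pick_alias(df, "target", aliases$target, f)),
        response = as.numeric(pick_alias(df, "response", aliases$response, f)),
        delay_s = as.numeric(pick_alias(df, "delay_s", aliases$delay_s, f)),
        skipped = as.logical(pick_alias(df, "skipped", aliases$skipped, f) %||%
                               FALSE)
      )
    })
    if (nrow(rows) == 0L) return(tibble::tibble())
    rows$participant <- pid
    rows$order <- seq_len(nrow(rows))
    rows[, c("participant", "order", "target", "response", "delay_s", "skipped")]
  })
  if (nrow(out) == 0L) {
    warning(sprintf("no participant JSON files found under '%s'", root))
    out <- tibble::tibble(participant = character(), order = integer(),
                          target = numeric(), response = numeric(),
                          delay_s = numeric(), skipped = logical())
  }
  if (!is.null(line_length_px)) {
    out$target <- out$target / line_length_px
    out$response <- out$response / line_length_px
  }
  attr(out, "extra_fields") <- extra
  out
}

#' Write a trial table in the participant-folder JSON layout
#'
#' Emits one directory per participant with one JSON file per
#' `set_size` trials (default 100 trials, i.e. ten 10-trial blocks),
#' mirroring the deposited-data layout so readers can be exercised
#' without the archive.
#'
#' @param trials Trial table.
#' @param root Output directory (created if needed).
#' @param set_size Trials per JSON file.
#' @return `root`, invisibly.
#' @export
write_participant_json <- function(trials, root, set_size = 100L) {
  dir.create(root, showWarnings = FALSE, recursive = TRUE)
  for (pid in unique(trials$participant)) {
    sub <- trials[trials$participant == pid, , drop = FALSE]
    sub <- sub[order(sub$order), , drop = FALSE]
    pdir <- file.path(root, pid)
    dir.create(pdir, showWarnings = FALSE)
    sets <- split(seq_len(nrow(sub)), ceiling(seq_len(nrow(sub)) / set_size))
    for (si in seq_along(sets)) {
      block <- sub[sets[[si]], c("order", "target", "response", "delay_s",
                                 "skipped")]
      jsonlite::write_json(block, file.path(pdir, sprintf("set_%03d.json", si)),
                           digits = NA, auto_unbox = FALSE)
    }
  }
  invisible(root)
}

#' Write a fit report as JSON
#'
#' Serializes a `landscape_fit` (parameters, cost trace, and when trials
#' are supplied the log-likelihood, AIC and BIC) together with the
#' package version and the config seed, so the fit is auditable and
#' reproducible.
#'
#' @param fit A `landscape_fit`.
#' @param path Output path.
#' @param trials Optional trial table for the likelihood block.
#' @param n_starts,n_runs Monte-Carlo design for the likelihood
#'   distribution set.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path, trials = NULL,
                             n_starts = 50L, n_runs = 300L) {
  report <- list(
    package_version = as.character(utils::packageVersion("memscape")),
    model = fit$config$model,
    seed = fit$config$seed,
    cost = fit$cost,
    k = fit$k,
    n_evals = fit$n_evals,
    converged = fit$converged,
    params = fit$params[c("beta", "sigma", "dt", "t0", "beta_p", "sigma_p",
                          "lambda_t")],
    drift = fit$landscape$drift,
    cost_trace = fit$trace
  )
  if (!is.null(trials)) {
    ms <- simulate_model_distributions(fit$landscape, fit$params,
                                       delays = sort(unique(trials$delay_s)),
                                       n_starts = n_starts, n_runs = n_runs,
                                       seed = fit$config$seed)
    ll <- log_likelihood(ms, trials)
    ic <- aic_bic(ll, fit$k, attr(ll, "n"))
    report$loglik <- as.numeric(ll)
    report$n <- attr(ll, "n")
    report$aic <- ic$aic
    report$bic <- ic$bic
  }
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
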