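#' Pipeline run configuration
#'
#' Bundles every option of the headless analysis pipeline
#' ([run_kinetics()]): experiment model, rate-extraction mode, transform,
#' blank handling, per-trace window overrides, and model options. The
#' Schnell-Mendoza mode is a global progress-curve fit and is only valid for
#' Michaelis-Menten experiments.
#'
#' @param mode Experiment model: `"mm"`, `"ic50"`, or `"hts"`.
#' @param rate_mode `"max_slope"`, `"linear"`, `"logarithmic"`, or
#'   `"schnell_mendoza"` (the last only with `mode = "mm"`).
#' @param windows Named list `label -> c(start, end)` of linear-fit window
#'   overrides.
#' @param transform Optional signal transform expression in `x`.
#' @param invert Multiply transformed signal by -1 (product-accumulation data
#'   entering the Schnell-Mendoza fit).
#' @param blank_label Optional blank column label; its rate (or fitted line,
#'   in Schnell-Mendoza mode) is subtracted.
#' @param delay Mixing dead-time (logarithmic mode only).
#' @param E0 Initial enzyme concentration for the quasi-steady-state check.
#' @param fixed Fixed 4-parameter-logistic parameters (ic50 mode).
#' @param x_scale `"linear"` or `"log10"` concentration axis (ic50 mode).
#' @param hts_threshold Hit threshold in standard deviations (hts mode).
#' @param seed Integer seed for any stochastic step.
#' @return A `run_config` list, validated.
#' @export
run_config <- function(mode = c("mm", "ic50", "hts"),
                       rate_mode = c("max_slope", "linear", "logarithmic",
                                     "schnell_mendoza"),
                       windows = NULL, transform = NULL, invert = FALSE,
                       blank_label = NULL, delay = 0, E0 = NULL,
                       fixed = list(), x_scale = c("linear", "log10"),
                       hts_threshold = 1, seed = 1L) {
  mode <- match.arg(mode)
  rate_mode <- match.arg(rate_mode)
  x_scale <- match.arg(x_scale)
  if (rate_mode == "schnell_mendoza" && mode != "mm") {
    stop("the Schnell-Mendoza global fit is only available in Michaelis-Menten mode",
         call. = FALSE)
  }
  structure(list(mode = mode, rate_mode = rate_mode, windows = windows,
                 transform = transform, invert = invert,
                 blank_label = blank_label, delay = delay, E0 = E0,
                 fixed = fixed, x_scale = x_scale,
                 hts_threshold = hts_threshold, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline on a kinetic-trace CSV
#'
#' Read, transform, extract initial rates (or run the global Schnell-Mendoza
#' fit), subtract the blank, fit the experiment model, and optionally write
#' the rate table, model-results table, and a log of every decision taken
#' (windows chosen, rows dropped, warnings). Deterministic for a given
#' configuration.
#'
#' @param input Path to a trace CSV (or literal CSV lines).
#' @param config A [run_config()].
#' @param out_dir Optional output directory; when given, writes
#'   `rates.csv`, `model.csv` and `run.log` there.
#' @return A list: `rates` (rate table), `fit` (model object or `NULL` for
#'   hts mode before flagging; the `hts_result` for hts), `results`
#'   (model/parameter/value/stderr tibble), `log` (character), `ok`
#'   (all fits converged).
#' @export
run_kinetics <- function(input, config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, paste0(...))
  catch_warn <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      note("WARN: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  note("mode=", config$mode, " rate_mode=", config$rate_mode,
       " seed=", config$seed)
  data <- catch_warn(read_kinetic_csv(input))
  note("read ", length(unique(data$label)), " trace(s)")
  if (!is.null(config$transform)) {
    data <- apply_transform(data, config$transform, invert = config$invert)
    note("applied transform ", sQuote(config$transform),
         if (config$invert) " (inverted)" else "")
  }

  ok <- TRUE
  if (config$rate_mode == "schnell_mendoza") {
    fit <- catch_warn(fit_schnell_mendoza(data, E0 = config$E0,
                                          blank_label = config$blank_label))
    rates <- tibble::tibble(
      label = names(fit$S0),
      concentration = unname(fit$S0),
      rate = fit$Vmax * unname(fit$S0) / (fit$KM + unname(fit$S0)),
      rate_stderr = NA_real_, mode = "schnell_mendoza",
      window_start = min(data$time), window_end = max(data$time))
    note(sprintf("global fit: KM=%.6g Vmax=%.6g", fit$KM, fit$Vmax))
    results <- tibble::tibble(model = "schnell_mendoza",
                              parameter = c("KM", "Vmax"),
                              value = c(fit$KM, fit$Vmax),
                              stderr = c(fit$stderr_KM, fit$stderr_Vmax))
  } else {
    rates <- catch_warn(initial_rates(data, mode = config$rate_mode,
                                      windows = config$windows,
                                      delay = config$delay,
                                      on_error = "warn"))
    n_fail <- length(unique(data$label)) - nrow(rates)
    if (n_fail > 0) { ok <- FALSE; note(n_fail, " trace(s) failed to fit") }
    purrr::pwalk(rates, function(label, window_start, window_end, ...) {
      note("trace ", sQuote(label), " window [", window_start, ", ",
           window_end, "]")
    })
    if (!is.null(config$blank_label)) {
      rates <- subtract_blank_rates(rates, config$blank_label)
      note("subtracted blank ", sQuote(config$blank_label))
    }
    fit <- NULL
    results <- switch(config$mode,
      mm = {
        fit <- catch_warn(fit_michaelis_menten(rates))
        tibble::tibble(model = "michaelis_menten",
                       parameter = c("Vmax", "KM"),
                       value = c(fit$Vmax, fit$KM),
                       stderr = c(fit$stderr_Vmax, fit$stderr_KM))
      },
      ic50 = {
        fit <- catch_warn(fit_logistic4(rates, fixed = config$fixed,
                                         x_scale = config$x_scale))
        td <- tidy(fit)
        tibble::tibble(model = "logistic4", parameter = td$term,
                       value = td$estimate, stderr = td$std.error)
      },
      hts = {
        fit <- hts_flag(rates, threshold_sd = config$hts_threshold)
        rates <- tidy(fit)
        tibble::tibble(model = "hts",
                       parameter = c("mean_rate", "sd_rate", "threshold_sd"),
                       value = c(fit$mean_rate, fit$sd_rate, fit$threshold_sd),
                       stderr = NA_real_)
      })
  }

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    if (config$mode == "hts") {
      readr::write_csv(rates, file.path(out_dir, "rates.csv"), progress = FALSE)
    } else {
      write_rate_table_csv(rates, file.path(out_dir, "rates.csv"))
    }
    readr::write_csv(results, file.path(out_dir, "model.csv"), progress = FALSE)
    writeLines(log_lines, file.path(out_dir, "run.log"))
    note("wrote outputs to ", out_dir)
  }
  list(rates = rates, fit = fit, results = results, log = log_lines, ok = ok)
}
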