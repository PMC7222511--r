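#' Simulation configuration for synthetic kinetic experiments
#'
#' Collects the ground-truth kinetic parameters and instrument model used by
#' the trace simulators. Defaults describe a typical plate-reader
#' Michaelis-Menten titration: `KM = 100`, `Vmax = 5` (concentration units
#' per minute), a doubling substrate series 0-320 with a 0-concentration
#' blank, 41 reads over 2 minutes, unit signal gain, a small constant
#' background, and Gaussian read noise of 0.05 signal units.
#'
#' @param KM,Vmax Ground-truth Michaelis-Menten parameters (> 0).
#' @param S0_list Titration design: initial substrate concentrations; 0 means
#'   a blank (background-only) well.
#' @param times Read times, strictly increasing, in the experiment's time
#'   unit (minutes by convention here).
#' @param noise_sd Gaussian read-noise standard deviation, absolute, in
#'   signal units.
#' @param background Constant instrument background added to every signal.
#' @param delay Mixing dead-time: the reaction starts `delay` time units
#'   before the first read (acquisition starts late).
#' @param signal_gain Concentration-to-signal factor (e.g. extinction
#'   coefficient times path length).
#' @param direction `"product_gain"` (signal rises as product accumulates,
#'   the default) or `"substrate_loss"` (signal falls with substrate).
#' @param seed Integer seed; the same seed reproduces byte-identical CSVs.
#' @return A `sim_config` list.
#' @export
sim_config <- function(KM = 100, Vmax = 5,
                       S0_list = c(0, 5, 10, 20, 40, 80, 160, 320),
                       times = seq(0, 2, by = 0.05),
                       noise_sd = 0.05, background = 0.05, delay = 0,
                       signal_gain = 1,
                       direction = c("product_gain", "substrate_loss"),
                       seed = 1L) {
  direction <- match.arg(direction)
  stopifnot(KM > 0, Vmax > 0, all(S0_list >= 0), all(diff(times) > 0),
            noise_sd >= 0, delay >= 0)
  structure(list(KM = KM, Vmax = Vmax, S0_list = S0_list, times = times,
                 noise_sd = noise_sd, background = background, delay = delay,
                 signal_gain = signal_gain, direction = direction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# True noiseless signal for one well. S0 = 0 is a blank: background only.
true_signal <- function(config, S0) {
  t_react <- config$times + config$delay
  if (S0 <= 0) return(rep(config$background, length(config$times)))
  s <- schnell_mendoza_curve(t_react, S0, config$KM, config$Vmax)
  conc <- if (config$direction == "substrate_loss") s else S0 - s
  config$background + config$signal_gain * conc
}

#' Simulate one Michaelis-Menten progress curve
#'
#' Evaluates the closed-form progress curve at the configured read times
#' (offset by the mixing dead-time), converts concentration to signal through
#' the gain/background/direction instrument model, and adds seeded Gaussian
#' read noise.
#'
#' @param config A [sim_config()].
#' @param S0 Initial substrate concentration for this well.
#' @param label Column label; default the concentration itself, as in the CSV
#'   dialect.
#' @return A trace tibble (`label`, `concentration`, `time`, `signal`) with
#'   the noiseless truth in attribute `truth`.
#' @export
simulate_progress_curve <- function(config, S0, label = as.character(S0)) {
  stopifnot(inherits(config, "sim_config"))
  mu <- true_signal(config, S0)
  sig <- mu + stats::rnorm(length(mu), 0, config$noise_sd)
  out <- tibble::tibble(label = label, concentration = abs(S0),
                        time = config$times, signal = sig)
  attr(out, "truth") <- mu
  out
}

simulate_dataset <- function(config, S0_list, labels = as.character(S0_list)) {
  set.seed(config$seed)
  purrr::map2_dfr(S0_list, labels, function(s0, lab) {
    simulate_progress_curve(config, s0, lab)
  })
}

#' Simulate a full Michaelis-Menten titration experiment
#'
#' Generates one trace per entry of `config$S0_list` (0 entries are blanks:
#' background plus noise only) and returns both the long dataset and the
#' wide CSV-dialect table, plus the ground-truth record, so every downstream
#' test is self-verifying.
#'
#' @param config A [sim_config()].
#' @param path Optional path; when given, the CSV-dialect file is written
#'   there.
#' @return A list: `data` (long tibble), `csv` (wide tibble, time column
#'   first, headers = concentrations), `truth` (tibble of true parameters
#'   and per-trace true initial rates `v0 = Vmax S0/(KM + S0)`), `path`.
#' @export
simulate_mm_experiment <- function(config = sim_config(), path = NULL) {
  stopifnot(inherits(config, "sim_config"))
  data <- simulate_dataset(config, config$S0_list)
  truth <- tibble::tibble(
    label = as.character(config$S0_list),
    parameter = "v0",
    value = ifelse(config$S0_list > 0,
                   config$Vmax * config$S0_list / (config$KM + config$S0_list), 0)
  )
  truth <- dplyr::bind_rows(
    tibble::tibble(label = "(global)", parameter = c("KM", "Vmax"),
                   value = c(config$KM, config$Vmax)),
    truth)
  finish_sim(data, truth, path)
}

finish_sim <- function(data, truth, path) {
  wide <- dataset_to_wide(data)
  if (!is.null(path)) write_kinetic_csv(wide, path)
  list(data = data, csv = wide, truth = truth, path = path)
}

#' Convert a long kinetic dataset to the wide CSV dialect (and write it)
#'
#' @param data Long dataset (`label`, `time`, `signal`).
#' @return `dataset_to_wide()`: a wide tibble, `time` first, one column per
#'   trace in first-appearance order.
#' @export
dataset_to_wide <- function(data) {
  labs <- unique(data$label)
  wide <- tidyr::pivot_wider(data[c("label", "time", "signal")],
                             names_from = "label", values_from = "signal")
  wide[c("time", labs)]
}

#' @rdname dataset_to_wide
#' @param wide Wide table, time column first.
#' @param path Output path.
#' @export
write_kinetic_csv <- function(wide, path) {
  out <- wide
  for (nm in names(out)) out[[nm]] <- sprintf("%.12g", out[[nm]])
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Simulate a dose-response (EC50/IC50) experiment
#'
#' Each inhibitor/activator concentration gets a straight-line trace whose
#' slope is the 4-parameter logistic response at that concentration, plus
#' noise; headers are the inhibitor concentrations.
#'
#' @param true_params Named list with `bottom`, `top`, `hill`, `midpoint`,
#'   and `x_scale` (`"linear"` or `"log10"`; midpoint lives on that scale).
#' @param concentrations Dose series (default 3-fold dilutions spanning
#'   1e-9 to 2e-4, molar-style units).
#' @param config A [sim_config()] (only `times`, `noise_sd`, `background`,
#'   `seed` are used).
#' @param path Optional CSV output path.
#' @return As [simulate_mm_experiment()]; `truth` holds the 4PL parameters
#'   and per-dose true slopes.
#' @export
simulate_ic50_experiment <- function(true_params = list(bottom = 0, top = 1,
                                                        hill = 1,
                                                        midpoint = -6,
                                                        x_scale = "log10"),
                                     concentrations = 1e-9 * 3^(0:11),
                                     config = sim_config(), path = NULL) {
  stopifnot(inherits(config, "sim_config"))
  x <- if (identical(true_params$x_scale, "log10")) log10(concentrations) else concentrations
  slopes <- logistic4_fun(x, true_params$bottom, true_params$top,
                          true_params$hill, true_params$midpoint)
  set.seed(config$seed)
  data <- purrr::map2_dfr(concentrations, slopes, function(cc, sl) {
    mu <- config$background + sl * config$times
    tibble::tibble(label = format(cc, scientific = TRUE, digits = 6),
                   concentration = cc, time = config$times,
                   signal = mu + stats::rnorm(length(mu), 0, config$noise_sd))
  })
  truth <- dplyr::bind_rows(
    tibble::tibble(label = "(global)",
                   parameter = c("bottom", "top", "hill", "midpoint"),
                   value = c(true_params$bottom, true_params$top,
                             true_params$hill, true_params$midpoint)),
    tibble::tibble(label = unique(data$label), parameter = "slope",
                   value = slopes))
  finish_sim(data, truth, path)
}

#' Simulate a high-throughput-screening plate
#'
#' Baseline well slopes are drawn from a seeded normal distribution; planted
#' outliers are offset by `z * rate_sd`. Traces are straight lines plus
#' read noise.
#'
#' @param n_wells Number of wells (>= 2), e.g. 96.
#' @param outliers Optional tibble/data frame with columns `index` and `z`:
#'   wells to offset by `z` baseline standard deviations.
#' @param config A [sim_config()] (`times`, `noise_sd`, `background`, `seed`).
#' @param rate_mean,rate_sd Baseline slope distribution (defaults 1 and 0.05:
#'   5% well-to-well variation).
#' @param path Optional CSV output path.
#' @return As [simulate_mm_experiment()]; `truth` holds each well's true
#'   slope and planted z-offset.
#' @export
simulate_hts_plate <- function(n_wells = 96, outliers = NULL,
                               config = sim_config(), rate_mean = 1,
                               rate_sd = 0.05, path = NULL) {
  stopifnot(n_wells >= 2)
  set.seed(config$seed)
  slopes <- stats::rnorm(n_wells, rate_mean, rate_sd)
  z <- rep(0, n_wells)
  if (!is.null(outliers) && nrow(as.data.frame(outliers))) {
    outliers <- as.data.frame(outliers)
    stopifnot(all(c("index", "z") %in% names(outliers)),
              all(outliers$index >= 1), all(outliers$index <= n_wells))
    z[outliers$index] <- outliers$z
    slopes[outliers$index] <- slopes[outliers$index] + outliers$z * rate_sd
  }
  labels <- sprintf("well %03d", seq_len(n_wells))
  data <- purrr::map_dfr(seq_len(n_wells), function(i) {
    mu <- config$background + slopes[i] * config$times
    tibble::tibble(label = labels[i], concentration = i,
                   time = config$times,
                   signal = mu + stats::rnorm(length(config$times), 0, config$noise_sd))
  })
  truth <- tibble::tibble(label = labels, parameter = "slope",
                          value = slopes, z = z)
  finish_sim(data, truth, path)
}
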