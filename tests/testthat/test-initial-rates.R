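line_trace <- function(slope, intercept = 1, t = 0:10) {
  tibble::tibble(label = "tr", concentration = 1, time = t,
                 signal = slope * t + intercept)
}

test_that("windowed linear fit recovers exact lines and flags bad windows", {
  r <- fit_linear_window(line_trace(2))
  expect_equal(r$rate, 2)
  expect_equal(r$stderr, 0)
  expect_equal(r$window, c(0, 10))
  expect_equal(fit_linear_window(line_trace(0, 5))$rate, 0)
  # inclusive window endpoints
  r2 <- fit_linear_window(line_trace(2), t_start = 3, t_end = 7)
  expect_equal(r2$window, c(3, 7))
  expect_length(r2$residuals, 5)
  expect_error(fit_linear_window(line_trace(2), 0, 1), "3 points")
  expect_error(fit_linear_window(
    tibble::tibble(time = c(1, 1, 1), signal = 1:3)), "time-variance")
})

test_that("noisy-line slope and stderr match the closed-form OLS oracle", {
  set.seed(42)
  t <- seq(0, 5, length.out = 20)
  y <- 1.5 * t + 0.7 + rnorm(20, 0, 0.1)
  r <- fit_linear_window(tibble::tibble(time = t, signal = y))
  o <- ols_oracle(t, y)
  expect_equal(r$rate, o$slope, tolerance = 1e-10)
  expect_equal(r$stderr, o$se, tolerance = 1e-10)
  expect_equal(r$params[["intercept"]], o$intercept, tolerance = 1e-10)
})

test_that("auto slope selection is exact on lines, either direction", {
  expect_equal(auto_max_slope(line_trace(-3))$rate, -3)
  expect_equal(auto_max_slope(line_trace(0.5))$rate, 0.5)
  expect_error(auto_max_slope(line_trace(2, t = 0:3)), "5 points")
  expect_error(auto_max_slope(
    tibble::tibble(time = c(0, 1, 1, 2, 3, 4), signal = 1:6)), "duplicate")
})

test_that("auto slope recovers v0 from a noiseless progress curve within 5%", {
  cfg <- sim_config(KM = 50, Vmax = 1, S0_list = 10,
                    times = seq(0, 3, by = 0.1), noise_sd = 0,
                    background = 0, direction = "substrate_loss")
  sim <- simulate_mm_experiment(cfg)
  r <- auto_max_slope(sim$data)
  v0 <- 1 * 10 / (50 + 10)
  expect_lt(abs(abs(r$rate) - v0) / v0, 0.05)
  expect_lt(r$rate, 0)  # substrate loss: decreasing trace, negative rate
})

test_that("auto slope excludes an initial lag artifact", {
  t <- seq(0, 6, by = 0.25)
  y <- ifelse(t < 2, 8, 8 + 4 * (t - 2))
  r <- auto_max_slope(tibble::tibble(time = t, signal = y))
  expect_gte(r$window[1], 2)
  expect_equal(r$rate, 4, tolerance = 0.02)
})

test_that("auto slope is shift-invariant and scale-equivariant", {
  set.seed(7)
  for (i in 1:5) {
    t <- seq(0, 10, length.out = 30)
    y <- 5 * (1 - exp(-0.3 * t)) + rnorm(30, 0, 0.01)
    tr <- tibble::tibble(time = t, signal = y)
    base <- auto_max_slope(tr)
    shifted <- auto_max_slope(dplyr::mutate(tr, signal = signal + 100))
    scaled <- auto_max_slope(dplyr::mutate(tr, signal = signal * -2.5))
    expect_equal(shifted$rate, base$rate, tolerance = 1e-8)
    expect_equal(scaled$rate, -2.5 * base$rate, tolerance = 1e-8)
  }
})

test_that("logarithmic fit reproduces b/t0 exactly, with and without delay", {
  t <- seq(0, 20, by = 0.5)
  tr <- tibble::tibble(time = t, signal = 1 + 2 * log(1 + t / 5))
  r <- fit_logarithmic(tr)
  expect_equal(r$rate, 0.4, tolerance = 1e-8)
  expect_equal(r$rate, r$params[["b"]] / r$params[["t0"]])  # identity
  # acquisition starts 3 time units after mixing
  tr_d <- tibble::tibble(time = t, signal = 1 + 2 * log(1 + (t + 3) / 5))
  r_d <- fit_logarithmic(tr_d, delay = 3)
  expect_equal(r_d$rate, 0.4, tolerance = 1e-8)
  # decreasing signal: fit on negated trace, rate negated
  tr_down <- tibble::tibble(time = t, signal = 10 - 2 * log(1 + t / 5))
  expect_equal(fit_logarithmic(tr_down)$rate, -0.4, tolerance = 1e-8)
  expect_error(fit_logarithmic(tr[1:3, ]), "4 points")
})

test_that("logarithmic mode beats a full-window line at S0 = 0.2 KM", {
  times <- seq(0, 20, by = 0.5)
  tr <- make_mm_trace(times, S0 = 10, KM = 50, Vmax = 1)
  v0 <- 1 * 10 / 60
  lin <- fit_linear_window(tr)
  logf <- fit_logarithmic(tr)
  err_lin <- abs(abs(lin$rate) - v0) / v0
  err_log <- abs(abs(logf$rate) - v0) / v0
  expect_lt(err_log, err_lin)
  expect_lt(err_log, 0.03)
})

test_that("all three modes agree on straight lines to 1e-3 relative", {
  for (slope in c(2, -3, 0.01)) {
    tr <- line_trace(slope)
    rates <- c(fit_linear_window(tr)$rate, auto_max_slope(tr)$rate,
               fit_logarithmic(tr)$rate)
    expect_equal(rates / slope, rep(1, 3), tolerance = 1e-3)
  }
})

test_that("residual diagnostics count runs and sign balance", {
  fake <- function(res) structure(
    list(residuals = res, rate = 0, stderr = 0, mode = "linear",
         window = c(0, 1), times = seq_along(res), fitted = res * 0),
    class = "initial_rate")
  d <- residual_diagnostics(fake(c(1, -1, 1, -1)))
  expect_equal(d$runs, 4L)
  expect_equal(d$frac_positive, 0.5)
  expect_equal(residual_diagnostics(fake(rep(2, 6)))$runs, 1L)
  # a line fit to a strongly curved segment leaves few residual runs
  t <- seq(0, 1, length.out = 20)
  r <- fit_linear_window(tibble::tibble(time = t, signal = t^2))
  expect_lte(residual_diagnostics(r)$runs, 3L)
})

test_that("initial_rates assembles the rate table over a dataset", {
  cfg <- sim_config(noise_sd = 0)
  sim <- simulate_mm_experiment(cfg)
  rt <- initial_rates(sim$data, mode = "max_slope")
  expect_equal(nrow(rt), 8)
  expect_named(rt, c("label", "concentration", "rate", "rate_stderr",
                     "mode", "window_start", "window_end"))
  expect_true(all(rt$mode == "max_slope"))
  # per-trace window overrides in linear mode
  rt2 <- initial_rates(sim$data, mode = "linear",
                       windows = list(`320` = c(0, 0.5)))
  expect_equal(rt2$window_end[rt2$label == "320"], 0.5)
  expect_equal(rt2$window_end[rt2$label == "40"], 2)
})

test_that("blank subtraction shifts rates by exactly the blank rate", {
  t <- 0:10
  ds <- dplyr::bind_rows(
    tibble::tibble(label = "0", concentration = 0, time = t,
                   signal = 0.3 * t + 1),
    tibble::tibble(label = "50", concentration = 50, time = t,
                   signal = 2.3 * t))
  rt <- initial_rates(ds, mode = "linear")
  out <- subtract_blank_rates(rt, "0")
  expect_equal(out$rate, 2.0, tolerance = 1e-12)
})
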