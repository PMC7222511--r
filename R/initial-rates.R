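#' @importFrom stats coef lm predict sd setNames smooth.spline vcov
NULL

new_initial_rate <- function(rate, stderr, mode, window, params, residuals,
                             fitted, times, label = NA_character_,
                             concentration = NA_real_) {
  structure(list(rate = rate, stderr = stderr, mode = mode, window = window,
                 params = params, residuals = residuals, fitted = fitted,
                 times = times, label = label, concentration = concentration),
            class = "initial_rate")
}

#' @export
print.initial_rate <- function(x, ...) {
  cat("<initial_rate> mode:", x$mode,
      sprintf(" rate: %.6g +/- %.3g", x$rate, x$stderr),
      sprintf(" window: [%g, %g]", x$window[1], x$window[2]), "\n")
  invisible(x)
}

trace_meta <- function(trace) {
  list(label = if ("label" %in% names(trace)) trace$label[1] else NA_character_,
       concentration = if ("concentration" %in% names(trace)) trace$concentration[1] else NA_real_)
}

#' Fit a straight line to a window of a kinetic trace
#'
#' Ordinary least squares over the points with `t_start <= time <= t_end`
#' (inclusive). The slope is the initial-rate estimate; its standard error
#' comes from the OLS covariance.
#'
#' @param trace One trace as a tibble with columns `time` and `signal`
#'   (optionally `label`, `concentration`, carried through).
#' @param t_start,t_end Window limits in the trace's time units; default the
#'   full trace.
#' @return An `initial_rate` object: slope, standard error, fitting window,
#'   intercept, residuals in time order. [generics::tidy()] gives the one-row
#'   rate-table form.
#' @export
fit_linear_window <- function(trace, t_start = -Inf, t_end = Inf) {
  stopifnot(all(c("time", "signal") %in% names(trace)))
  sel <- trace$time >= t_start & trace$time <= t_end
  tt <- trace$time[sel]; yy <- trace$signal[sel]
  if (length(tt) < 3) stop("fewer than 3 points in fitting window", call. = FALSE)
  if (stats::var(tt) == 0) stop("zero time-variance in fitting window", call. = FALSE)
  fit <- lm(yy ~ tt)
  # summary.lm warns on exact data ("essentially perfect fit"); a zero
  # stderr is the correct answer there
  sm <- suppressWarnings(summary(fit))$coefficients
  meta <- trace_meta(trace)
  new_initial_rate(
    rate = unname(coef(fit)[2]),
    stderr = if (nrow(sm) >= 2) unname(sm[2, 2]) else NA_real_,
    mode = "linear",
    window = c(min(tt), max(tt)),
    params = c(intercept = unname(coef(fit)[1])),
    residuals = unname(stats::residuals(fit)),
    fitted = unname(stats::fitted(fit)),
    times = tt,
    label = meta$label, concentration = meta$concentration
  )
}

#' Automatic maximum-slope initial rate
#'
#' The default extraction mode: a cubic smoothing spline (smoothness chosen by
#' generalized cross-validation) is fit to the trace, the time of maximal
#' absolute spline derivative is located (earliest wins on ties), and the
#' fitting window is the contiguous run of points around it whose derivative
#' magnitude is at least half the maximum, expanded outward to a minimum of
#' `min_points`. A straight line over that window gives the rate, so lag
#' artifacts and the depleted tail of the trace are excluded automatically.
#'
#' @inheritParams fit_linear_window
#' @param min_points Minimum window size (default 5).
#' @param spar Optional smoothing parameter override passed to
#'   [stats::smooth.spline()]; `NULL` uses generalized cross-validation.
#' @param df_max Flexibility cap applied when the trace is noisy: if the
#'   cross-validated spline uses more than `df_max` equivalent degrees of
#'   freedom on data it does not interpolate, it is refit at `df_max`.
#'   Initial-rate progress curves are low-curvature, and an under-smoothed
#'   derivative turns noise wiggles into spurious steep windows.
#' @return An `initial_rate` with mode `"max_slope"`.
#' @export
auto_max_slope <- function(trace, min_points = 5, spar = NULL, df_max = 4) {
  stopifnot(all(c("time", "signal") %in% names(trace)))
  n <- nrow(trace)
  if (n < 5) stop("need at least 5 points for automatic slope selection", call. = FALSE)
  if (anyDuplicated(trace$time)) stop("duplicate time points", call. = FALSE)
  ss <- tryCatch({
    fit <- if (is.null(spar)) {
      suppressWarnings(smooth.spline(trace$time, trace$signal, cv = FALSE))
    } else {
      suppressWarnings(smooth.spline(trace$time, trace$signal, spar = spar))
    }
    if (is.null(spar)) {
      resid_sd <- sqrt(mean((predict(fit, trace$time)$y - trace$signal)^2))
      rng <- diff(range(trace$signal))
      if (rng > 0 && resid_sd > 1e-6 * rng && fit$df > df_max) {
        fit <- suppressWarnings(smooth.spline(trace$time, trace$signal,
                                              df = df_max))
      }
    }
    fit
  },
    error = function(e) stop("spline smoothing failed: ", conditionMessage(e),
                             call. = FALSE)
  )
  d1 <- abs(predict(ss, trace$time, deriv = 1)$y)
  i_star <- which.max(d1)            # which.max takes the earliest maximum
  thr <- 0.5 * d1[i_star]
  lo <- i_star
  while (lo > 1 && d1[lo - 1] >= thr) lo <- lo - 1
  hi <- i_star
  while (hi < n && d1[hi + 1] >= thr) hi <- hi + 1
  # expand to the minimum window size, preferring the side with the larger
  # derivative magnitude (stay in the signal-limited region)
  while (hi - lo + 1 < min_points) {
    left_ok <- lo > 1; right_ok <- hi < n
    if (!left_ok && !right_ok) break
    go_left <- left_ok && (!right_ok || d1[lo - 1] >= d1[hi + 1])
    if (go_left) lo <- lo - 1 else hi <- hi + 1
  }
  out <- fit_linear_window(trace, trace$time[lo], trace$time[hi])
  out$mode <- "max_slope"
  out
}

#' Logarithmic integrated Michaelis-Menten initial rate
#'
#' Fits the logarithmic approximation of the integrated Michaelis-Menten
#' equation, `y = y0 + b * log(1 + t/t0)` with `b > 0`, `t0 > 0`, by
#' constrained Levenberg-Marquardt least squares with a multi-start over `t0`.
#' The initial rate is the derivative at the instant of mixing, `b/t0`.
#' Decreasing traces are fit on the negated signal and the rate negated, which
#' keeps the positivity constraint on `b` meaningful. A mixing dead-time
#' `delay` shifts the fitted time axis (observed times become `t + delay`) so
#' the rate is extrapolated back to the true mixing instant.
#'
#' The rate standard error is propagated from the (b, t0) covariance by the
#' first-order delta method, including their correlation.
#'
#' @inheritParams fit_linear_window
#' @param delay Time between mixing and the first read, in the trace's time
#'   units (default 0).
#' @return An `initial_rate` with mode `"logarithmic"`; `params` holds
#'   `y0`, `b`, `t0`, `delay`.
#' @export
fit_logarithmic <- function(trace, delay = 0) {
  stopifnot(all(c("time", "signal") %in% names(trace)), delay >= 0)
  if (nrow(trace) < 4) stop("need at least 4 points for the logarithmic fit", call. = FALSE)
  tt <- trace$time + delay
  yy <- trace$signal
  if (!is_monotone_within_noise(yy)) {
    warning("trace is not monotone within noise; logarithmic fit may be unstable",
            call. = FALSE)
  }
  decreasing <- unname(coef(lm(yy ~ tt))[2]) < 0
  y_fit <- if (decreasing) -yy else yy

  span <- diff(range(tt))
  resid_fn <- function(p) p[["y0"]] + p[["b"]] * log1p(tt / p[["t0"]]) - y_fit
  t0_grid <- span * 10^seq(-2, 1, length.out = 5)
  best <- NULL
  for (t0_init in t0_grid) {
    b_init <- (y_fit[length(y_fit)] - y_fit[1]) / log1p(tt[length(tt)] / t0_init)
    if (!is.finite(b_init) || b_init <= 0) b_init <- 1e-6
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = list(y0 = y_fit[1], b = b_init, t0 = t0_init),
        lower = c(-Inf, 1e-12, 1e-12), fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance)) best <- fit
  }
  if (is.null(best)) stop("logarithmic fit did not converge for any start", call. = FALSE)
  p <- coef(best)
  rate <- p[["b"]] / p[["t0"]]
  cv <- tryCatch(vcov(best), error = function(e) matrix(NA_real_, 3, 3))
  grad <- c(1 / p[["t0"]], -p[["b"]] / p[["t0"]]^2)   # d(b/t0)/d(b, t0)
  se <- sqrt(drop(t(grad) %*% cv[2:3, 2:3] %*% grad))
  if (!is.finite(se)) se <- 0
  resid <- y_fit - (p[["y0"]] + p[["b"]] * log1p(tt / p[["t0"]]))
  if (decreasing) { rate <- -rate; resid <- -resid }
  meta <- trace_meta(trace)
  new_initial_rate(
    rate = rate, stderr = se, mode = "logarithmic",
    window = c(min(trace$time), max(trace$time)),
    params = c(y0 = if (decreasing) -p[["y0"]] else p[["y0"]],
               b = p[["b"]], t0 = p[["t0"]], delay = delay),
    residuals = resid, fitted = yy - resid, times = trace$time,
    label = meta$label, concentration = meta$concentration
  )
}

is_monotone_within_noise <- function(y) {
  d <- diff(y)
  if (!length(d)) return(TRUE)
  tol <- 2 * sd(d)
  all(d >= -tol) || all(d <= tol)
}

#' Residual randomness diagnostics
#'
#' Summarizes the residuals of an initial-rate fit: the number of sign runs
#' and the fraction of positive residuals. A well-chosen window gives a
#' random-looking residual plot (many runs, balanced signs); systematic
#' curvature collapses the run count.
#'
#' @param rate An `initial_rate` object.
#' @return A one-row tibble with `n`, `runs`, `frac_positive`.
#' @export
residual_diagnostics <- function(rate) {
  stopifnot(inherits(rate, "initial_rate"))
  r <- rate$residuals
  if (!length(r)) stop("no residuals stored on this fit", call. = FALSE)
  s <- sign(r)
  s[s == 0] <- 1
  tibble::tibble(
    n = length(r),
    runs = 1L + sum(diff(s) != 0),
    frac_positive = mean(r > 0)
  )
}

#' Initial rates for every trace of a dataset
#'
#' Maps one of the per-trace extraction modes over a long kinetic dataset and
#' assembles the rate table that all endpoint models consume.
#'
#' @param data Long dataset from [read_kinetic_csv()] or the simulators.
#' @param mode `"max_slope"` (default), `"linear"`, or `"logarithmic"`.
#' @param windows Optional per-trace window overrides for the linear mode: a
#'   named list `label -> c(start, end)`; traces without an entry use the full
#'   trace.
#' @param delay Mixing dead-time, used by the logarithmic mode only.
#' @param on_error `"stop"` (default) or `"warn"`; with `"warn"`, traces whose
#'   fit fails are dropped from the table with a warning.
#' @return A rate-table tibble: `label`, `concentration`, `rate`,
#'   `rate_stderr`, `mode`, `window_start`, `window_end`.
#' @export
#' @examples
#' sim <- simulate_mm_experiment(sim_config(noise_sd = 0))
#' initial_rates(sim$data, mode = "max_slope")
initial_rates <- function(data, mode = c("max_slope", "linear", "logarithmic"),
                          windows = NULL, delay = 0,
                          on_error = c("stop", "warn")) {
  mode <- match.arg(mode)
  on_error <- match.arg(on_error)
  traces <- split_traces(data)
  fits <- purrr::imap(traces, function(tr, lab) {
    f <- function() {
      switch(mode,
        max_slope = auto_max_slope(tr),
        linear = {
          w <- windows[[lab]] %||% c(-Inf, Inf)
          fit_linear_window(tr, w[1], w[2])
        },
        logarithmic = fit_logarithmic(tr, delay = delay))
    }
    if (on_error == "stop") f()
    else tryCatch(f(), error = function(e) {
      warning("trace ", sQuote(lab), " failed: ", conditionMessage(e), call. = FALSE)
      NULL
    })
  })
  fits <- purrr::compact(fits)
  if (!length(fits)) stop("all traces failed to fit", call. = FALSE)
  purrr::map_dfr(fits, tidy_initial_rate)
}

tidy_initial_rate <- function(x) {
  tibble::tibble(
    label = x$label, concentration = x$concentration, rate = x$rate,
    rate_stderr = x$stderr, mode = x$mode,
    window_start = x$window[1], window_end = x$window[2]
  )
}

#' @export
tidy.initial_rate <- function(x, ...) tidy_initial_rate(x)

#' @export
glance.initial_rate <- function(x, ...) {
  tibble::tibble(rate = x$rate, rate_stderr = x$stderr, mode = x$mode,
                 n = length(x$residuals),
                 rss = sum(x$residuals^2))
}

#' @export
augment.initial_rate <- function(x, ...) {
  tibble::tibble(time = x$times,
                 signal = x$fitted + x$residuals,
                 .fitted = x$fitted, .resid = x$residuals)
}
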