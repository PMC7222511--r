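#' Principal-branch Lambert W of exp(u)
#'
#' Evaluates `W0(e^u)` stably for any real `u`. For moderate `u` this is the
#' ordinary Lambert W of `exp(u)`; for large `u`, where `exp(u)` overflows,
#' the defining relation `w + log(w) = u` is solved directly by a safeguarded
#' Newton iteration started at the asymptotic expansion `u - log(u)`. This is
#' the form needed by the closed-form Michaelis-Menten progress curve, whose
#' Lambert argument is an exponential of the (possibly large) ratio `S0/KM`.
#'
#' @param u Numeric vector.
#' @return `W0(exp(u))`, same length as `u`.
#' @export
lambert_w0_exp <- function(u) {
  out <- numeric(length(u))
  # exp(u) underflows: W0(z) ~ z(1 - z) for z -> 0, relative error < 1e-300
  tiny <- u < -700
  out[tiny] <- 0
  small <- !tiny & u <= 50
  if (any(small)) {
    # Halley iteration on w e^w = z, z = exp(u) (no overflow for u <= 50)
    z <- exp(u[small])
    w <- ifelse(z < 3, z / (1 + z), log(z) - log(pmax(log(z), 1.5)))
    for (k in 1:100) {
      ew <- exp(w)
      f <- w * ew - z
      step <- f / (ew * (w + 1) - (w + 2) * f / (2 * w + 2))
      w <- w - step
      if (all(abs(step) <= 1e-15 * (abs(w) + 1e-300))) break
    }
    out[small] <- w
  }
  big <- u > 50
  if (any(big)) {
    # solve w + log(w) = u directly; Newton from the asymptotic expansion
    ub <- u[big]
    w <- ub - log(ub)
    for (k in 1:50) {
      step <- (ub - w - log(w)) / (1 + 1 / w)
      w <- w + step
      if (all(abs(step) <= 1e-15 * abs(w))) break
    }
    out[big] <- w
  }
  out
}

#' Closed-form Michaelis-Menten progress curve
#'
#' The Schnell-Mendoza closed-form solution of the irreversible
#' Michaelis-Menten rate law `dS/dt = -Vmax S / (KM + S)`:
#' \deqn{S(t) = K_M \, W_0\!\left(\frac{S_0}{K_M}
#'   \exp\frac{S_0 - V_{max} t}{K_M}\right)}
#' evaluated on the principal branch of the Lambert W (omega) function. The
#' whole computation runs in the log domain (`u = log(S0/KM) + (S0 - Vmax
#' t)/KM`) so large `S0/KM` ratios never overflow. At `t = 0` the Lambert
#' identity `W(x e^x) = x` gives `S(0) = S0` exactly.
#'
#' @param t Times, all `>= 0`.
#' @param S0 Initial substrate concentration (> 0).
#' @param KM Michaelis constant (> 0), same concentration units as `S0`.
#' @param Vmax Maximal velocity (> 0), concentration per time unit.
#' @return Substrate concentrations at `t`, strictly decreasing to 0.
#' @export
#' @examples
#' schnell_mendoza_curve(c(0, 10, 100), S0 = 10, KM = 50, Vmax = 1)
schnell_mendoza_curve <- function(t, S0, KM, Vmax) {
  stopifnot(all(t >= 0), S0 > 0, KM > 0, Vmax > 0)
  u <- log(S0 / KM) + (S0 - Vmax * t) / KM
  s <- KM * lambert_w0_exp(u)
  if (any(!is.finite(s))) stop("non-finite substrate concentration computed", call. = FALSE)
  s
}

#' Quasi-steady-state validity ratio
#'
#' The closed-form progress curve (like every quasi-steady-state treatment)
#' is valid only when `E0 / (KM + S0)` is much less than 1, where `E0` is the
#' initial enzyme concentration. Returns that ratio; [fit_schnell_mendoza()]
#' warns when it reaches `0.1`.
#'
#' @param E0,KM,S0 Positive reals in consistent concentration units.
#' @return The ratio `E0 / (KM + S0)`.
#' @export
check_qss_validity <- function(E0, KM, S0) {
  stopifnot(all(E0 > 0), all(KM > 0), all(S0 > 0))
  E0 / (KM + S0)
}

#' Global Schnell-Mendoza fit of KM and Vmax
#'
#' Fits the closed-form Michaelis-Menten progress curve globally to every
#' trace of a substrate-depletion dataset: `KM` and `Vmax` are shared across
#' traces, while each trace's initial substrate concentration `S0` is a free
#' parameter initialized from the concentration parsed out of its column
#' header (nominal concentrations carry pipetting error). Minimization is
#' Levenberg-Marquardt over the concatenated, unweighted residuals with
#' positivity bounds on every parameter; standard errors come from the
#' covariance at the optimum.
#'
#' If `blank_label` is given, a straight line fitted to that trace is first
#' subtracted pointwise from every other trace, and the blank is excluded
#' from the fit. If `E0` is given, the quasi-steady-state ratio
#' `E0/(KM + S0)` is computed per trace ([check_qss_validity()]) and a
#' warning is emitted when the maximum reaches `qss_warn` (default 0.1).
#'
#' @param data Long dataset whose signals are substrate concentrations
#'   decreasing over time (apply [apply_transform()] with `invert = TRUE`
#'   first for product-accumulation data).
#' @param E0 Optional initial enzyme concentration, for the validity check.
#' @param blank_label Optional label of a blank trace to subtract.
#' @param qss_warn Warn when the quasi-steady-state ratio reaches this value.
#' @return An `sm_fit` object; `tidy()` gives the parameter table (KM, Vmax,
#'   per-trace S0) with standard errors, `glance()` the fit summary including
#'   `qss_ratio_max`.
#' @export
fit_schnell_mendoza <- function(data, E0 = NULL, blank_label = NULL,
                                qss_warn = 0.1) {
  traces <- split_traces(data)
  if (!is.null(blank_label)) {
    if (!blank_label %in% names(traces)) {
      stop("blank label ", sQuote(blank_label), " not found", call. = FALSE)
    }
    bl <- traces[[blank_label]]
    bfit <- lm(signal ~ time, data = bl)
    traces <- traces[setdiff(names(traces), blank_label)]
    traces <- purrr::map(traces, function(tr) {
      tr$signal <- tr$signal - unname(predict(bfit, newdata = tr["time"]))
      tr
    })
  }
  if (length(traces) < 1) stop("no traces to fit", call. = FALSE)

  med_slope <- purrr::map_dbl(traces, function(tr) {
    stats::median(diff(tr$signal) / diff(tr$time))
  })
  if (stats::median(med_slope) > 0) {
    stop("traces increase over time; substrate-depletion data required ",
         "(product-accumulation signals must be inverted by multiplying by -1,",
         " see apply_transform(invert = TRUE))", call. = FALSE)
  }

  s0_nominal <- purrr::map_dbl(traces, function(tr) {
    cc <- trace_meta(tr)$concentration
    if (is.finite(cc) && cc > 0) cc else max(tr$signal)
  })
  s0_init <- pmax(s0_nominal, 1e-8)
  km_init <- stats::median(s0_init)
  span <- max(purrr::map_dbl(traces, ~ max(.x$time))) -
          min(purrr::map_dbl(traces, ~ min(.x$time)))
  drop0 <- max(purrr::map_dbl(traces, ~ .x$signal[1] - .x$signal[nrow(.x)]))
  vmax_init <- max(drop0 / span, 1e-8)

  resid_fn <- function(p) {
    km <- p[[1]]; vmax <- p[[2]]
    unlist(purrr::imap(traces, function(tr, lab) {
      s0 <- p[[paste0("S0_", lab)]]
      schnell_mendoza_curve(tr$time - min(tr$time), s0, km, vmax) - tr$signal
    }), use.names = FALSE)
  }
  par0 <- c(list(KM = km_init, Vmax = vmax_init),
            setNames(as.list(s0_init), paste0("S0_", names(traces))))
  best <- NULL
  for (km_mult in c(0.2, 1, 5)) {
    p0 <- par0; p0$KM <- km_init * km_mult
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = rep(1e-12, length(p0)),
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance)) best <- fit
  }
  if (is.null(best)) stop("global Schnell-Mendoza fit did not converge", call. = FALSE)
  p <- coef(best)
  cv <- tryCatch(vcov(best), error = function(e) matrix(NA_real_, length(p), length(p)))
  se <- sqrt(pmax(diag(cv), 0))

  per_trace_rss <- purrr::imap_dbl(traces, function(tr, lab) {
    s0 <- p[[paste0("S0_", lab)]]
    sum((schnell_mendoza_curve(tr$time - min(tr$time), s0, p[["KM"]], p[["Vmax"]]) -
           tr$signal)^2)
  })

  s0_hat <- p[grepl("^S0_", names(p))]
  qss_ratio_max <- NA_real_
  if (!is.null(E0)) {
    qss_ratio_max <- max(check_qss_validity(E0, p[["KM"]], s0_hat))
    if (qss_ratio_max >= qss_warn) {
      warning(sprintf(
        "quasi-steady-state ratio E0/(KM + S0) reaches %.3g (>= %.3g); the closed-form solution may not be valid",
        qss_ratio_max, qss_warn), call. = FALSE)
    }
  }
  structure(list(
    KM = p[["KM"]], Vmax = p[["Vmax"]],
    stderr_KM = se[[1]], stderr_Vmax = se[[2]],
    S0 = setNames(unname(s0_hat), sub("^S0_", "", names(s0_hat))),
    stderr_S0 = setNames(unname(se[-(1:2)]), sub("^S0_", "", names(s0_hat))),
    per_trace_rss = per_trace_rss, qss_ratio_max = qss_ratio_max,
    E0 = E0, deviance = best$deviance, n = length(resid_fn(as.list(p))),
    traces = traces
  ), class = "sm_fit")
}

#' @export
print.sm_fit <- function(x, ...) {
  cat("<sm_fit> global closed-form Michaelis-Menten progress-curve fit\n")
  cat(sprintf("  KM   = %.6g +/- %.3g\n", x$KM, x$stderr_KM))
  cat(sprintf("  Vmax = %.6g +/- %.3g\n", x$Vmax, x$stderr_Vmax))
  cat(sprintf("  %d trace(s); residual sum of squares %.4g\n",
              length(x$S0), x$deviance))
  if (is.finite(x$qss_ratio_max %||% NA_real_)) {
    cat(sprintf("  max E0/(KM+S0) = %.3g\n", x$qss_ratio_max))
  }
  invisible(x)
}

#' @export
tidy.sm_fit <- function(x, ...) {
  tibble::tibble(
    term = c("KM", "Vmax", paste0("S0[", names(x$S0), "]")),
    estimate = c(x$KM, x$Vmax, unname(x$S0)),
    std.error = c(x$stderr_KM, x$stderr_Vmax, unname(x$stderr_S0))
  )
}

#' @export
glance.sm_fit <- function(x, ...) {
  tibble::tibble(KM = x$KM, Vmax = x$Vmax, stderr_KM = x$stderr_KM,
                 stderr_Vmax = x$stderr_Vmax, deviance = x$deviance,
                 n_traces = length(x$S0), n_points = x$n,
                 qss_ratio_max = x$qss_ratio_max)
}
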