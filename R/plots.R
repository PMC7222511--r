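#' Plot a kinetic trace with its initial-rate fit
#'
#' The trace as points, the fitted segment as a line over its window, and the
#' residuals of the fit in a rug-like lower panel replacement: residuals are
#' returned by [residual_diagnostics()] and [augment()] for separate
#' plotting, so this panel shows trace + fit only.
#'
#' @param trace One trace tibble (`time`, `signal`).
#' @param rate An `initial_rate` for that trace.
#' @return A ggplot.
#' @export
plot_trace_fit <- function(trace, rate) {
  stopifnot(inherits(rate, "initial_rate"))
  fit_df <- tibble::tibble(time = rate$times, fitted = rate$fitted)
  ggplot2::ggplot(trace, ggplot2::aes(x = .data$time, y = .data$signal)) +
    ggplot2::geom_point(colour = "grey40", size = 1) +
    ggplot2::geom_line(data = fit_df,
                       ggplot2::aes(x = .data$time, y = .data$fitted),
                       colour = "red", linewidth = 0.8) +
    ggplot2::labs(x = "time", y = "signal",
                  subtitle = sprintf("%s rate = %.4g ± %.2g",
                                     rate$mode, rate$rate, rate$stderr)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mm_fit <- function(object, ...) {
  s_grid <- seq(0, max(object$data$concentration) * 1.05, length.out = 200)
  curve_df <- tibble::tibble(concentration = s_grid,
                             rate = predict(object, s_grid))
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$concentration, y = .data$rate)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$rate - .data$rate_stderr,
                                        ymax = .data$rate + .data$rate_stderr),
                           width = 0) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve_df, colour = "red") +
    ggplot2::labs(x = "substrate concentration", y = "initial rate",
                  subtitle = sprintf("Vmax = %.4g ± %.2g, KM = %.4g ± %.2g",
                                     object$Vmax, object$stderr_Vmax,
                                     object$KM, object$stderr_KM)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.logistic_fit <- function(object, ...) {
  xg <- seq(min(object$x), max(object$x), length.out = 200)
  curve_df <- tibble::tibble(x = xg, rate = predict(object, xg))
  df <- tibble::tibble(x = object$x, rate = object$data$rate,
                       rate_stderr = object$data$rate_stderr)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$rate)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$rate - .data$rate_stderr,
                                        ymax = .data$rate + .data$rate_stderr),
                           width = 0) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve_df, colour = "red") +
    ggplot2::labs(x = if (object$x_scale == "log10") "log10 concentration"
                      else "concentration",
                  y = "initial rate",
                  subtitle = sprintf("midpoint = %.4g, hill = %.3g",
                                     object$midpoint, object$hill)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.hts_result <- function(object, ...) {
  df <- object$data
  df$well <- seq_len(nrow(df))
  m <- object$mean_rate; s <- object$sd_rate; k <- object$threshold_sd
  ggplot2::ggplot(df, ggplot2::aes(x = .data$well, y = .data$rate,
                                   colour = .data$flag)) +
    ggplot2::geom_hline(yintercept = m) +
    ggplot2::geom_hline(yintercept = c(m - k * s, m + k * s),
                        linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(above = "red", below = "blue",
                                            none = "grey40")) +
    ggplot2::labs(x = "well", y = "initial rate") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sm_fit <- function(object, ...) {
  obs <- dplyr::bind_rows(object$traces)
  fitted <- purrr::imap_dfr(object$traces, function(tr, lab) {
    tg <- seq(min(tr$time), max(tr$time), length.out = 100)
    tibble::tibble(label = lab, time = tg,
                   signal = schnell_mendoza_curve(tg - min(tr$time),
                                                  object$S0[[lab]],
                                                  object$KM, object$Vmax))
  })
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$time, y = .data$signal,
                                    group = .data$label)) +
    ggplot2::geom_point(colour = "grey50", size = 0.8) +
    ggplot2::geom_line(data = fitted, colour = "red") +
    ggplot2::labs(x = "time", y = "substrate concentration",
                  subtitle = sprintf("global fit: KM = %.4g, Vmax = %.4g",
                                     object$KM, object$Vmax)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
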