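# Weights from the rate-table stderr column: inverse variance, with rows of
# zero stderr given the smallest positive stderr in the table; if no row has a
# positive stderr the fit is unweighted (and the parameter covariance then
# uses the residual variance instead of the supplied sigmas).
rate_weights <- function(stderr) {
  pos <- stderr[is.finite(stderr) & stderr > 0]
  if (!length(pos)) return(list(w = rep(1, length(stderr)), absolute = FALSE))
  s <- ifelse(is.finite(stderr) & stderr > 0, stderr, min(pos))
  list(w = 1 / s^2, absolute = TRUE)
}

# Parameter covariance for a weighted nls.lm fit. With absolute sigmas,
# cov = (J' W J)^-1 on the weighted residual Jacobian; otherwise the usual
# residual-variance estimate. nls.lm was run on sqrt(w)-scaled residuals, so
# its hessian is J' W J already.
nlslm_cov <- function(fit, absolute) {
  h <- fit$hessian
  cv <- tryCatch(solve(h), error = function(e) matrix(NA_real_, nrow(h), ncol(h)))
  if (!absolute) {
    df <- length(fit$fvec) - length(coef(fit))
    cv <- cv * sum(fit$fvec^2) / max(df, 1)
  }
  cv
}

#' Fit the Michaelis-Menten equation to a rate table
#'
#' Weighted nonlinear least squares of `v = Vmax [S] / (KM + [S])` to the
#' initial rates, with weights `1/stderr^2` so that the per-trace fitting
#' errors propagate into the parameter estimates and their standard errors.
#' Rows at concentration 0 carry no Michaelis-Menten information (they are
#' the blank role) and are excluded. A log-grid multi-start on `KM` over the
#' concentration range guards against local minima.
#'
#' @param table Rate table (columns `concentration`, `rate`, `rate_stderr`).
#' @return An `mm_fit` object with `Vmax`, `KM` and standard errors;
#'   `tidy()`/`glance()`/`autoplot()` methods available.
#' @export
fit_michaelis_menten <- function(table) {
  stopifnot(all(c("concentration", "rate", "rate_stderr") %in% names(table)))
  tb <- table[table$concentration > 0, , drop = FALSE]
  if (length(unique(tb$concentration)) < 3) {
    stop("need at least 3 distinct positive concentrations", call. = FALSE)
  }
  s <- tb$concentration; v <- tb$rate
  wt <- rate_weights(tb$rate_stderr)
  sw <- sqrt(wt$w)
  resid_fn <- function(p) sw * (p[["Vmax"]] * s / (p[["KM"]] + s) - v)
  km_grid <- exp(seq(log(min(s)), log(max(s) * 10), length.out = 7))
  vmax_init <- max(abs(v)) * sign(v[which.max(abs(v))])
  best <- NULL
  for (km0 in km_grid) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = list(Vmax = vmax_init, KM = km0),
                         lower = c(-Inf, 1e-12), fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance)) best <- fit
  }
  if (is.null(best)) stop("Michaelis-Menten fit did not converge", call. = FALSE)
  p <- coef(best)
  cv <- nlslm_cov(best, wt$absolute)
  se <- sqrt(pmax(diag(cv), 0))
  structure(list(
    Vmax = p[["Vmax"]], KM = p[["KM"]],
    stderr_Vmax = se[[1]], stderr_KM = se[[2]],
    deviance = best$deviance, n = length(v), data = tb, weights = wt$w
  ), class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("<mm_fit> Michaelis-Menten fit (", x$n, " rates)\n", sep = "")
  cat(sprintf("  Vmax = %.6g +/- %.3g\n  KM   = %.6g +/- %.3g\n",
              x$Vmax, x$stderr_Vmax, x$KM, x$stderr_KM))
  invisible(x)
}

#' @export
tidy.mm_fit <- function(x, ...) {
  tibble::tibble(term = c("Vmax", "KM"),
                 estimate = c(x$Vmax, x$KM),
                 std.error = c(x$stderr_Vmax, x$stderr_KM))
}

#' @export
glance.mm_fit <- function(x, ...) {
  tibble::tibble(Vmax = x$Vmax, KM = x$KM, stderr_Vmax = x$stderr_Vmax,
                 stderr_KM = x$stderr_KM, deviance = x$deviance, n = x$n)
}

#' Predict Michaelis-Menten velocities
#' @param object An `mm_fit`.
#' @param concentration Substrate concentrations.
#' @param ... Unused.
#' @export
predict.mm_fit <- function(object, concentration, ...) {
  object$Vmax * concentration / (object$KM + concentration)
}

logistic4_fun <- function(x, bottom, top, hill, midpoint) {
  bottom + (top - bottom) / (1 + 10^(hill * (midpoint - x)))
}

#' Fit the 4-parameter logistic (EC50/IC50) model to a rate table
#'
#' Weighted fit of the dose-response sigmoid
#' `y = bottom + (top - bottom) / (1 + 10^(hill (midpoint - x)))`
#' over `x =` concentration (linear scale) or `x = log10(concentration)`.
#' On the log10 scale the fitted `midpoint` is the pIC50-style log-midpoint.
#' Any of `top`, `bottom`, `hill` (typically 1) can be fixed; fixed
#' parameters are excluded from the optimization and reported with standard
#' error 0. Weights are `1/stderr^2` as in [fit_michaelis_menten()].
#' Zero-concentration rows are dropped with a warning on the log10 scale
#' (no finite logarithm).
#'
#' @param table Rate table (columns `concentration`, `rate`, `rate_stderr`).
#' @param fixed Named list of parameters to fix, e.g. `list(hill = 1)`.
#' @param x_scale `"linear"` or `"log10"`.
#' @return A `logistic_fit` object; `tidy()` lists all four parameters with
#'   a `fixed` flag.
#' @export
fit_logistic4 <- function(table, fixed = list(), x_scale = c("linear", "log10")) {
  stopifnot(all(c("concentration", "rate", "rate_stderr") %in% names(table)))
  x_scale <- match.arg(x_scale)
  allowed <- c("bottom", "top", "hill", "midpoint")
  if (length(fixed) && !all(names(fixed) %in% allowed)) {
    stop("fixable parameters are ", paste(allowed, collapse = ", "), call. = FALSE)
  }
  if (length(fixed) >= 4) stop("all four parameters fixed; nothing to fit", call. = FALSE)
  tb <- table
  if (x_scale == "log10") {
    if (any(tb$concentration <= 0)) {
      warning("dropping ", sum(tb$concentration <= 0),
              " zero-concentration row(s): no finite log10", call. = FALSE)
      tb <- tb[tb$concentration > 0, , drop = FALSE]
    }
    x <- log10(tb$concentration)
  } else {
    x <- tb$concentration
  }
  if (nrow(tb) < 4) stop("need at least 4 usable rows", call. = FALSE)
  y <- tb$rate
  wt <- rate_weights(tb$rate_stderr)
  sw <- sqrt(wt$w)

  free <- setdiff(c("bottom", "top", "hill", "midpoint"), names(fixed))
  full_par <- function(p) {
    out <- c(as.list(p), fixed)
    list(bottom = out$bottom, top = out$top, hill = out$hill,
         midpoint = out$midpoint)
  }
  resid_fn <- function(p) {
    q <- full_par(p)
    sw * (logistic4_fun(x, q$bottom, q$top, q$hill, q$midpoint) - y)
  }
  slope_sign <- suppressWarnings(stats::cor(x, y))
  if (!is.finite(slope_sign)) slope_sign <- 1
  init_full <- list(bottom = min(y), top = max(y),
                    hill = if (slope_sign >= 0) 1 else -1,
                    midpoint = stats::median(x))
  mid_grid <- seq(min(x), max(x), length.out = 5)
  best <- NULL
  for (m0 in mid_grid) for (h0 in unique(c(init_full$hill, 1, -1))) {
    p0 <- init_full; p0$midpoint <- m0; p0$hill <- h0
    p0 <- p0[free]
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance)) best <- fit
  }
  if (is.null(best)) stop("4-parameter logistic fit did not converge", call. = FALSE)
  p <- coef(best)
  q <- full_par(as.list(p))
  if (isTRUE(all.equal(q$top, q$bottom))) {
    stop("degenerate fit: top == bottom (flat dose-response)", call. = FALSE)
  }
  cv <- nlslm_cov(best, wt$absolute)
  se_free <- sqrt(pmax(diag(cv), 0))
  se <- setNames(rep(0, 4), c("bottom", "top", "hill", "midpoint"))
  se[names(p)] <- se_free
  structure(list(
    bottom = q$bottom, top = q$top, hill = q$hill, midpoint = q$midpoint,
    stderr = se, fixed = names(fixed), x_scale = x_scale,
    deviance = best$deviance, n = length(y), data = tb, x = x, weights = wt$w
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("<logistic_fit> 4-parameter logistic (x scale: ", x$x_scale, ")\n", sep = "")
  print(tidy.logistic_fit(x))
  invisible(x)
}

#' @export
tidy.logistic_fit <- function(x, ...) {
  terms <- c("bottom", "top", "hill", "midpoint")
  tibble::tibble(
    term = terms,
    estimate = c(x$bottom, x$top, x$hill, x$midpoint),
    std.error = unname(x$stderr[terms]),
    fixed = terms %in% x$fixed
  )
}

#' @export
glance.logistic_fit <- function(x, ...) {
  tibble::tibble(bottom = x$bottom, top = x$top, hill = x$hill,
                 midpoint = x$midpoint, x_scale = x$x_scale,
                 deviance = x$deviance, n = x$n)
}

#' Predict 4-parameter logistic response
#' @param object A `logistic_fit`.
#' @param x Values on the scale the model was fit on (concentration or
#'   log10 concentration, per `object$x_scale`).
#' @param ... Unused.
#' @export
predict.logistic_fit <- function(object, x, ...) {
  logistic4_fun(x, object$bottom, object$top, object$hill, object$midpoint)
}

#' Flag high-throughput-screening hits by standard-deviation threshold
#'
#' Computes the mean and sample standard deviation (n - 1 denominator) of all
#' initial rates on a plate and flags each well strictly above
#' `mean + threshold_sd * sd` as `"above"` (activator-like) or strictly below
#' `mean - threshold_sd * sd` as `"below"` (inhibitor-like); all others are
#' `"none"`. A rate exactly at a threshold is not flagged. If the standard
#' deviation is 0 no well is flagged.
#'
#' @param table Rate table (columns `label`, `rate` at minimum).
#' @param threshold_sd Positive threshold in standard-deviation units
#'   (typically 1).
#' @return An `hts_result`; `tidy()` gives per-well flags, `glance()` the
#'   plate mean/sd.
#' @export
hts_flag <- function(table, threshold_sd = 1) {
  stopifnot(all(c("label", "rate") %in% names(table)), threshold_sd > 0)
  if (nrow(table) < 2) stop("need at least 2 rates", call. = FALSE)
  m <- mean(table$rate)
  s <- sd(table$rate)
  flag <- rep("none", nrow(table))
  if (s > 0) {
    flag[table$rate > m + threshold_sd * s] <- "above"
    flag[table$rate < m - threshold_sd * s] <- "below"
  }
  structure(list(
    mean_rate = m, sd_rate = s, threshold_sd = threshold_sd,
    data = tibble::tibble(table, flag = flag)
  ), class = "hts_result")
}

#' @export
print.hts_result <- function(x, ...) {
  cat(sprintf("<hts_result> %d wells; mean rate %.6g, sd %.4g, threshold %g sd\n",
              nrow(x$data), x$mean_rate, x$sd_rate, x$threshold_sd))
  cat("  flagged above:", sum(x$data$flag == "above"),
      " below:", sum(x$data$flag == "below"), "\n")
  invisible(x)
}

#' @export
tidy.hts_result <- function(x, ...) x$data

#' @export
glance.hts_result <- function(x, ...) {
  tibble::tibble(mean_rate = x$mean_rate, sd_rate = x$sd_rate,
                 threshold_sd = x$threshold_sd, n = nrow(x$data),
                 n_above = sum(x$data$flag == "above"),
                 n_below = sum(x$data$flag == "below"))
}

#' Subtract a blank sample's rate from a rate table
#'
#' Subtracts the blank trace's fitted rate from every other rate and combines
#' the standard errors in quadrature; the blank row is removed.
#'
#' @param table Rate table containing `blank_label`.
#' @param blank_label Label of the blank row.
#' @return The corrected rate table without the blank row.
#' @export
subtract_blank_rates <- function(table, blank_label) {
  stopifnot(all(c("label", "rate", "rate_stderr") %in% names(table)))
  i <- which(table$label == blank_label)
  if (!length(i)) stop("blank label ", sQuote(blank_label), " not in table", call. = FALSE)
  i <- i[1]
  out <- table[-i, , drop = FALSE]
  out$rate <- out$rate - table$rate[i]
  out$rate_stderr <- sqrt(out$rate_stderr^2 + table$rate_stderr[i]^2)
  out
}
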