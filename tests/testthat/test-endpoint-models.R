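rate_table <- function(conc, rate, stderr = rep(0.01, length(conc)),
                       label = as.character(conc)) {
  tibble::tibble(label = label, concentration = conc, rate = rate,
                 rate_stderr = stderr, mode = "linear",
                 window_start = 0, window_end = 1)
}

mm_v <- function(s, vmax, km) vmax * s / (km + s)

test_that("Michaelis-Menten fit is exact on hyperbolic data", {
  s <- c(5, 10, 25, 50, 100, 320)
  fit <- fit_michaelis_menten(rate_table(s, mm_v(s, 10, 25)))
  expect_equal(fit$Vmax, 10, tolerance = 1e-6)
  expect_equal(fit$KM, 25, tolerance = 1e-6)
  # zero-concentration rows are the blank role and are excluded
  fit0 <- fit_michaelis_menten(rate_table(c(0, s), c(99, mm_v(s, 10, 25))))
  expect_equal(fit0$KM, 25, tolerance = 1e-6)
  expect_error(fit_michaelis_menten(rate_table(c(5, 5, 10), c(1, 1, 2))),
               "3 distinct")
  # fitted curve is monotone increasing in [S]
  sg <- seq(0.1, 1000, length.out = 200)
  expect_true(all(diff(predict(fit, sg)) > 0))
})

test_that("weighted fit agrees with a brute-force grid-search oracle", {
  set.seed(21)
  s <- c(5, 10, 20, 40, 80, 160, 320)   # 0-320 titration design
  stderr <- runif(7, 0.005, 0.05)
  v <- mm_v(s, 10, 25) + rnorm(7, 0, stderr)
  tb <- rate_table(s, v, stderr)
  fit <- fit_michaelis_menten(tb)
  o <- mm_grid_oracle(s, v, 1 / stderr^2)
  expect_equal(fit$Vmax, o$Vmax, tolerance = 0.005)
  expect_equal(fit$KM, o$KM, tolerance = 0.005)
})

test_that("a grossly perturbed but down-weighted point barely moves the fit", {
  s <- c(5, 10, 20, 40, 80, 160, 320)
  v <- mm_v(s, 10, 25)
  clean <- fit_michaelis_menten(rate_table(s, v))
  v2 <- v; v2[3] <- v[3] * 5
  stderr2 <- rep(0.01, 7); stderr2[3] <- 1   # 100x larger uncertainty
  dirty <- fit_michaelis_menten(rate_table(s, v2, stderr2))
  expect_lt(abs(dirty$KM - clean$KM) / clean$KM, 0.01)
  expect_lt(abs(dirty$Vmax - clean$Vmax) / clean$Vmax, 0.01)
})

test_that("inflating all rate stderrs inflates parameter stderrs only", {
  set.seed(22)
  s <- c(5, 10, 20, 40, 80, 160, 320)
  stderr <- rep(0.02, 7)
  v <- mm_v(s, 10, 25) + rnorm(7, 0, stderr)
  f1 <- fit_michaelis_menten(rate_table(s, v, stderr))
  f2 <- fit_michaelis_menten(rate_table(s, v, 10 * stderr))
  expect_equal(f2$KM, f1$KM, tolerance = 1e-6)
  expect_equal(f2$Vmax, f1$Vmax, tolerance = 1e-6)
  expect_equal(f2$stderr_KM / f1$stderr_KM, 10, tolerance = 1e-3)
  expect_equal(f2$stderr_Vmax / f1$stderr_Vmax, 10, tolerance = 1e-3)
})

l4 <- function(x, bottom, top, hill, mid) {
  bottom + (top - bottom) / (1 + 10^(hill * (mid - x)))
}

test_that("4PL fit recovers exact dose-response data and its symmetry", {
  conc <- 10^seq(-9, -3, by = 0.5)
  y <- l4(log10(conc), 0, 100, 1, -6)
  tb <- rate_table(conc, y)
  fit <- fit_logistic4(tb, x_scale = "log10")
  expect_equal(fit$bottom, 0, tolerance = 1e-6)
  expect_equal(fit$top, 100, tolerance = 1e-6)
  expect_equal(fit$hill, 1, tolerance = 1e-6)
  expect_equal(fit$midpoint, -6, tolerance = 1e-6)
  # midpoint prediction is (top+bottom)/2 regardless of hill
  expect_equal(predict(fit, fit$midpoint), (fit$top + fit$bottom) / 2,
               tolerance = 1e-10)
  # prediction monotone with sign(hill)
  xg <- seq(-10, -2, length.out = 100)
  expect_true(all(diff(predict(fit, xg)) * sign(fit$hill) > 0))
})

test_that("fixing the Hill slope at the true value changes nothing", {
  conc <- 10^seq(-9, -3, by = 0.5)
  y <- l4(log10(conc), 0, 100, 1, -6)
  free <- fit_logistic4(rate_table(conc, y), x_scale = "log10")
  fixed <- fit_logistic4(rate_table(conc, y), fixed = list(hill = 1),
                         x_scale = "log10")
  expect_equal(fixed$midpoint, free$midpoint, tolerance = 1e-6)
  expect_equal(unname(fixed$stderr["hill"]), 0)
  expect_lt(abs(fixed$deviance - free$deviance), 1e-9)
  td <- tidy(fixed)
  expect_identical(td$fixed, c(FALSE, FALSE, TRUE, FALSE))
})

test_that("4PL guards: zero concentrations on log scale, over-constraint", {
  conc <- c(0, 10^seq(-8, -4, by = 1))
  y <- l4(log10(pmax(conc, 1e-12)), 0, 1, 1, -6)
  expect_warning(fit_logistic4(rate_table(conc, y), x_scale = "log10"),
                 "zero-concentration")
  expect_error(fit_logistic4(rate_table(conc, y),
                             fixed = list(bottom = 0, top = 1, hill = 1,
                                          midpoint = -6)),
               "fixed")
  expect_error(fit_logistic4(rate_table(conc[1:3], y[1:3])), "4 usable")
})

test_that("HTS flags match hand arithmetic and the z-score oracle", {
  res <- hts_flag(rate_table(1:4, c(1, 1, 1, 10)), threshold_sd = 1)
  expect_equal(res$mean_rate, 3.25)
  expect_equal(res$sd_rate, 4.5)
  expect_identical(res$data$flag, c("none", "none", "none", "above"))
  # all equal -> sd 0 -> nothing flagged
  expect_true(all(hts_flag(rate_table(1:4, rep(2, 4)))$data$flag == "none"))
  expect_error(hts_flag(rate_table(1, 1)), "2 rates")
  set.seed(23)
  for (i in 1:1000) {
    n <- sample(4:24, 1)
    rates <- rnorm(n) * 10^runif(1, -3, 3)
    k <- runif(1, 0.5, 3)
    res <- hts_flag(rate_table(seq_len(n), rates), threshold_sd = k)
    expect_identical(res$data$flag, zscore_oracle(rates, k))
  }
})

test_that("blank-rate subtraction combines errors in quadrature", {
  tb <- rate_table(c(0, 10), c(0.5, 2.0), c(0.1, 0.2),
                   label = c("blank", "A"))
  out <- subtract_blank_rates(tb, "blank")
  expect_equal(nrow(out), 1)
  expect_equal(out$rate, 1.5)
  expect_equal(out$rate_stderr, sqrt(0.04 + 0.01), tolerance = 1e-12)
  expect_error(subtract_blank_rates(tb, "nope"), "not in table")
  # zero blank rate changes nothing but removes the row
  tb0 <- rate_table(c(0, 10), c(0, 2.0), c(0, 0.2), label = c("b", "A"))
  expect_equal(subtract_blank_rates(tb0, "b")$rate, 2.0)
  # subtracting then adding back restores the original rates
  restored <- dplyr::mutate(out, rate = rate + tb$rate[1])
  expect_equal(restored$rate, tb$rate[-1])
})
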