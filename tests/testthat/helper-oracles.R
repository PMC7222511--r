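# Independent oracles used across the suite. These are deliberately naive
# textbook implementations, kept separate from the package code paths they
# check.

# Closed-form OLS slope and its standard error.
ols_oracle <- function(t, y) {
  n <- length(t)
  tm <- mean(t); ym <- mean(y)
  sxx <- sum((t - tm)^2)
  slope <- sum((t - tm) * (y - ym)) / sxx
  intercept <- ym - slope * tm
  sse <- sum((y - intercept - slope * t)^2)
  list(slope = slope, intercept = intercept,
       se = sqrt(sse / (n - 2) / sxx))
}

# Brute-force z-score hit classifier (sample sd, strict inequalities).
zscore_oracle <- function(rates, k) {
  m <- mean(rates); s <- stats::sd(rates)
  if (s == 0) return(rep("none", length(rates)))
  ifelse(rates > m + k * s, "above",
         ifelse(rates < m - k * s, "below", "none"))
}

# Adaptive Runge-Kutta integration of the Michaelis-Menten rate law.
ode_mm_oracle <- function(t, S0, KM, Vmax) {
  out <- deSolve::lsoda(
    y = c(S = S0), times = t,
    func = function(t, y, p) list(-p$Vmax * y / (p$KM + y)),
    parms = list(KM = KM, Vmax = Vmax),
    rtol = 1e-10, atol = 1e-12 * S0)
  unname(out[, "S"])
}

# Three-stage grid search minimizing the weighted Michaelis-Menten SSE.
mm_grid_oracle <- function(s, v, w) {
  sse <- function(vmax, km) sum(w * (vmax * s / (km + s) - v)^2)
  v_rng <- c(0.3, 3) * max(abs(v))
  k_rng <- c(min(s) / 10, max(s) * 10)
  best <- c(Vmax = NA, KM = NA); best_sse <- Inf
  for (stage in 1:4) {
    vg <- seq(v_rng[1], v_rng[2], length.out = 41)
    kg <- exp(seq(log(k_rng[1]), log(k_rng[2]), length.out = 41))
    for (vv in vg) for (kk in kg) {
      cur <- sse(vv, kk)
      if (cur < best_sse) { best_sse <- cur; best <- c(Vmax = vv, KM = kk) }
    }
    dv <- diff(v_rng) / 40; dk <- exp(diff(log(k_rng)) / 40)
    v_rng <- best[["Vmax"]] + c(-2, 2) * dv
    k_rng <- best[["KM"]] * c(1 / dk^2, dk^2)
  }
  as.list(best)
}

# One noiseless/noisy progress-curve trace without going through sim_config
# (used where a test wants full control of the noise model).
make_mm_trace <- function(times, S0, KM, Vmax, noise_sd = 0,
                          label = as.character(S0)) {
  s <- initrate::schnell_mendoza_curve(times, S0, KM, Vmax)
  tibble::tibble(label = label, concentration = S0, time = times,
                 signal = s + stats::rnorm(length(s), 0, noise_sd))
}
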