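---
title: "Extracting initial rates from continuous kinetic traces: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting initial rates from continuous kinetic traces: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(initrate)
library(dplyr)
```

## The problem

Continuous enzyme assays record signal (absorbance, fluorescence) against
time for many wells at once. Downstream kinetics — Michaelis–Menten
titrations, EC50/IC50 dose–response series, activator/inhibitor screens —
consume one number per well: the *initial rate* $v_0$, the slope of the
progress curve at the instant of mixing, before substrate depletion bends the
trace. Picking the linear region by eye in a spreadsheet is slow and biased,
especially at substrate concentrations below $K_M$ where curvature begins
immediately. This package automates that reduction and carries the
uncertainty of every per-well fit into the experiment-level model.

A dataset is a tidy tibble — one row per (trace, time) observation with
columns `label`, `concentration`, `time`, `signal` — read from the common
plate-export CSV dialect: the first column is time, each further column is a
trace whose header contains the titrant concentration (`parse_concentration()`
takes the first numeric token that is not glued to the end of a word, so
`"kinase1 40 uM"` means 40). Signals can be converted to concentration units
through a user transform in one variable `x`, evaluated under a strict
arithmetic-only grammar (numbers, `x`, `+ - * / ^`, parentheses) — a
deliberate design choice over `eval()`: a transform box should never be a
code-execution surface.

## Per-trace rate extraction

Three modes produce a rate, a standard error, and residuals per trace.

**Windowed linear fit** (`fit_linear_window`). Ordinary least squares over
the points inside a user window (inclusive endpoints); the slope's standard
error comes from the OLS covariance. This is the reference against which the
other modes are judged on straight-line data.

**Automatic maximum-slope selection** (`auto_max_slope`, the default). A
cubic smoothing spline is fit to the trace — smoothness by generalized
cross-validation, since traces arrive at many noise levels and an absolute
smoothing constant would not transfer — and the point of maximal absolute
spline derivative is located. Cross-validation alone under-smooths noisy,
nearly flat traces (the low-substrate wells of a titration): the derivative
of an under-smoothed spline tracks noise wiggles, and a max-slope criterion
then locks onto a spurious steep segment. Because initial-rate progress
curves are low-curvature by nature, the spline's flexibility is therefore
capped at `df_max` (default 4 equivalent degrees of freedom) whenever the
spline does not interpolate the data; noiseless traces keep the full
cross-validated fit, so sharp features like lag kinks remain localized when
the data genuinely support them. The fitting window is the contiguous run of
points whose derivative magnitude stays at or above 50% of that maximum,
expanded outward (preferring the steeper side) to at least 5 points, and a
straight line is fit there. The 50%/5-point rule is a design choice made
once: it recovers the full window on exact lines (constant derivative), it
excludes both lag artifacts at the start and the depleted tail, and it is
deterministic. Ties in the derivative maximum go to the earliest time, since
"initial rate" means the earliest signal-limited region. Working on the
absolute derivative makes decreasing traces (substrate-loss signals)
first-class: their rates come out negative.

**Logarithmic integrated-rate fit** (`fit_logarithmic`). When no early
segment is convincingly linear — low $[S]_0/K_M$, fast enzymes — a straight
line systematically underestimates $v_0$. The trace is instead fit to the
logarithmic approximation of the integrated Michaelis–Menten equation,

$$y = y_0 + b \,\ln(1 + t/t_0), \qquad b > 0,\; t_0 > 0,$$

whose derivative at the mixing instant gives the rate $v_0 = b/t_0$. Fitting
is bounded Levenberg–Marquardt with a five-point multi-start on $t_0$ over a
log grid spanning 1%–1000% of the time span (the model is ill-conditioned in
$t_0$ alone; the multi-start makes the straight-line limit $t_0 \to \infty$,
$b/t_0 \to$ slope reachable). Initialization: $y_0$ from the first point,
$b$ from matching the last point at the candidate $t_0$. The standard error
of $b/t_0$ uses the first-order delta method with the full $2\times 2$
covariance of $(b, t_0)$, correlation included — the two are strongly
anti-correlated, and ignoring that overstates the error several-fold.
Decreasing traces are fit on the negated signal and the rate negated, which
keeps the $b > 0$ constraint meaningful. A mixing dead-time $\Delta$ (the
instrument's delay between reaction start and first read) shifts the fitted
time axis, $t \mapsto t + \Delta$; shifting the axis or moving the derivative
evaluation point are algebraically identical for this model, and the
axis-shift convention is the one implemented.

Residual quality is summarized by `residual_diagnostics()` (sign runs and
positive fraction): a well-chosen window leaves a random-looking residual
plot, while curvature collapses the run count.

## The closed-form progress curve and the global fit

The irreversible Michaelis–Menten rate law
$dS/dt = -V_{max} S/(K_M + S)$ has the closed-form time-domain solution

$$S(t) = K_M \, W_0\!\left(\frac{S_0}{K_M}
  \exp\frac{S_0 - V_{max}\,t}{K_M}\right),$$

with $W_0$ the principal branch of the Lambert W (omega) function
(`schnell_mendoza_curve()`). Numerically the argument is an exponential of
$S_0/K_M$, which overflows long before the parameters become unphysical, so
the package evaluates $W_0(e^u)$ directly from
$u = \ln(S_0/K_M) + (S_0 - V_{max}t)/K_M$: Halley iteration on
$w e^w = e^u$ for $u \le 50$, and for larger $u$ a safeguarded Newton
iteration on the log-domain form $w + \ln w = u$ started from the asymptotic
expansion $u - \ln u$. Both branches converge to machine precision; tests
pin the branch seam and the defining identity. At $t = 0$ the identity
$W(x e^x) = x$ returns $S_0$ exactly.

`fit_schnell_mendoza()` fits this curve *globally*: $K_M$ and $V_{max}$ are
shared across all traces while each trace's $S_0$ is a free parameter
initialized from its header concentration. Freeing $S_0$ is deliberate —
nominal concentrations carry pipetting error, and treating initial
concentrations as fitted parameters is the modern integrated-rate practice;
it also makes the fit robust to small offsets after blank subtraction.
Residuals are unweighted (all points are reads of the same instrument), the
optimizer is bounded Levenberg–Marquardt with a small multi-start on $K_M$
(0.2×, 1×, 5× of the median $S_0$), and parameter errors come from the
covariance at the optimum. When a blank trace is named, a straight line
fitted to it is subtracted pointwise from every other trace first.

The closed form inherits the quasi-steady-state assumption: it is trusted
only while $E_0/(K_M + S_0) \ll 1$. `check_qss_validity()` returns the
ratio, and the global fit warns when it reaches 0.1 — the paper-trail
convention "much less than one" needs an operational cutoff, and one order
of magnitude is the conventional reading; the threshold is an argument, not
a constant. Since the fit only sees substrate depletion, increasing traces
are rejected with a pointer to `apply_transform(invert = TRUE)` for
product-accumulation signals.

## Endpoint models and error propagation

All experiment-level models consume the rate table (label, concentration,
rate, stderr) and weight each rate by $1/\sigma_i^2$ — inverse-variance
weighting is how "errors propagate" in least squares. Rows with $\sigma_i =
0$ (exact fits) borrow the smallest positive $\sigma$ in the table rather
than acquiring infinite weight; if no row has an error the fit is unweighted.
Parameter covariance treats the supplied $\sigma_i$ as *absolute*:
$\mathrm{cov} = (J^\top W J)^{-1}$ without rescaling by residual variance.
That choice makes propagation honest — doubling every rate error doubles the
parameter errors while leaving the point estimates untouched — where the
residual-rescaled convention would silently discard the supplied errors'
scale. Unweighted fits fall back to the usual residual-variance covariance.

* `fit_michaelis_menten()`: $v = V_{max}[S]/(K_M+[S])$, multi-start on
  $K_M$ over a log grid of the concentration range. Zero-concentration rows
  are excluded — they are the blank role and carry no information about the
  hyperbola.
* `fit_logistic4()`: $y = \mathrm{bottom} + (\mathrm{top} -
  \mathrm{bottom})/(1 + 10^{\,\mathrm{hill}\,(\mathrm{mid} - x)})$ with $x$
  either concentration or $\log_{10}$ concentration. On the log scale the
  fitted midpoint is the pIC50-style log-midpoint; the fit itself is
  invariant to that labeling. Any of top/bottom/hill (typically hill = 1)
  can be fixed; fixed parameters leave the optimization and report standard
  error 0. Zero concentrations have no finite log and are dropped with a
  warning on the log scale.
* `hts_flag()`: plate mean and *sample* standard deviation ($n-1$; plates
  are samples of a well population) with strict inequalities at
  $\bar v \pm k\,s$ — a rate exactly at the threshold is not a hit; $s = 0$
  flags nothing.
* `subtract_blank_rates()`: blank rate subtracted, errors combined in
  quadrature, blank row removed.

Replicate columns at the same concentration are fit separately and enter the
endpoint model as separate rows; aggregation is left to the caller, who
knows whether replicates are technical or biological.

## The synthetic-trace generator

`sim_config()` plus `simulate_mm_experiment()`, `simulate_ic50_experiment()`
and `simulate_hts_plate()` generate complete experiments in the same CSV
dialect the reader consumes, with ground truth riding alongside, so every
end-to-end test is self-verifying. The defaults describe one realistic
plate-reader titration, chosen once: $K_M = 100$, $V_{max} = 5$
(concentration per minute), the doubling series 0, 5, 10, 20, 40, 80, 160,
320 with the 0 column as a background-only blank, 41 reads over 2 minutes
(modest depletion — about 10% at the lowest substrate — which is precisely
the regime where automatic window choice matters), unit gain, background
0.05, and i.i.d. Gaussian read noise of 0.05 signal units (~1% of the
smallest trace's amplitude). Noise lives in signal space, not concentration
space, mimicking photometric read noise. The mixing dead-time is implemented
by evaluating the true curve at `times + delay`: acquisition starts late,
which is the scenario a dead-time box addresses.

What the generator does *not* emulate: coupled-assay lag phases, enzyme
inactivation, product inhibition, well-position (edge/drift) effects, or
heteroscedastic detector noise. Tests passing on these fixtures therefore
demonstrate correctness of the estimators under the stated model, not
robustness to every pathology of real plates — the residual diagnostics and
manual window overrides exist for exactly those cases.

Example sizes used throughout the test-suite and the reproduction script
were chosen to make each check sharp but quick: 1000 random parameter draws
for the Lambert identity, nine $S_0/K_M$ decades against the ODE oracle,
4 × 51-point traces for the global fit, 10 seeded replicates for the
coverage check, 96-well plates for screening.

## A worked end-to-end pass

```{r end-to-end}
sim <- simulate_mm_experiment(sim_config(noise_sd = 0))
rates <- initial_rates(sim$data, mode = "max_slope")
fit <- fit_michaelis_menten(rates)
glance(fit)
```

The logarithmic mode tightens the low-concentration rates (a full-window
line underestimates $v_0$ once depletion reaches a few percent):

```{r log-mode}
glance(fit_michaelis_menten(initial_rates(sim$data, mode = "logarithmic")))
```

## Known limitations

* The auto-window heuristic (50% of maximal derivative, minimum 5 points) is
  one defensible convention, not a universal optimum; traces with double
  kinetic phases should be fit with explicit windows.
* The logarithmic model assumes a monotone trace; it warns, but does not
  refuse, on oscillating data.
* The closed-form fit implements the plain irreversible Michaelis–Menten
  law; reversibility, product inhibition, and enzyme inactivation are out of
  scope.
* `pracma::lambertWp` is used only as an independent cross-check in the test
  suite; the package's own $W_0(e^u)$ evaluator exists because the fit needs
  vectorized, overflow-safe evaluation at extreme arguments.
* Time units are metadata: rates are reported in signal units per input time
  unit, and no seconds/minutes conversion is ever applied.
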