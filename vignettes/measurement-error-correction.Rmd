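---
title: "Correcting classical exposure measurement error: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting classical exposure measurement error: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcsimex)
```

## The problem

When a continuous exposure $X$ is observed only through an error-prone
measurement $W = X + \varepsilon$, with $\varepsilon$ independent of $X$,
mean zero and variance $\tau^2$ (*classical* or random measurement error),
the regression coefficient of the outcome on $W$ is biased toward the null.
In a linear model adjusted for covariates $C$ the bias is multiplicative:
the naive coefficient converges to $\lambda \beta$ with attenuation factor

$$\lambda = \frac{\sigma^2_{X|C}}{\sigma^2_{X|C} + \tau^2},$$

the variance of the true exposure *given the covariates* over the same plus
the error variance. The marginal analogue $\mathrm{Var}(X)/\mathrm{Var}(W)$
is the *reliability* of the measurement; the two coincide only when the
exposure is independent of the covariates. For logistic regression no exact
factorization exists, but for small-to-moderate exposure effects or small
error variance the naive log-odds coefficient is attenuated by approximately
the same factor, and `rcsimex` treats it that way throughout.

`rcsimex` implements the two corrections that need only an assumption about
$\tau^2$ — no validation sample with the true exposure:

* **Regression calibration (RC)** divides the naive coefficient by the
  estimated attenuation factor,
  $\hat\beta_{RC} = \hat\beta_{naive} \cdot
  \hat\sigma^2_{W|C} / (\hat\sigma^2_{W|C} - \hat\tau^2)$, where
  $\hat\sigma^2_{W|C}$ is the residual variance of $W$ regressed on the
  covariates. Applied identically to the linear slope and (Rosner-style,
  approximately) to the logistic log-odds coefficient. Covariate
  coefficients are left uncorrected.
* **Simulation-extrapolation (SIMEX)** *adds* noise: for multipliers
  $\zeta \in \{0.5, 1, 1.5, 2\}$ it forms $W + \sqrt{\zeta\tau^2}\,
  \varepsilon^*$, refits the outcome model 100 times per $\zeta$, averages
  the coefficients, fits a polynomial trend in $\zeta$ (including the naive
  point at $\zeta = 0$), and extrapolates to $\zeta = -1$, the point of zero
  total error.

$\tau^2$ itself comes either from replicate measurements — the sample
variance of each individual's $k$ replicates, averaged over individuals
(`estimate_tau2_replicates()`), which is unbiased under classical error —
or is supplied as known, the sensitivity-analysis setting.

## Why SIMEX is systematically biased and RC is not

RC inverts the attenuation identity exactly, so given a correct $\tau^2$ it
is unbiased for the linear model up to small-sample ratio noise. SIMEX's
extrapolant is a working model: the true attenuation curve
$\beta\,\sigma^2_{X|C} / (\sigma^2_{X|C} + (1+\zeta)\tau^2)$ is a rational
function of $\zeta$, which no quadratic reproduces outside the fitted
range. On the noise-free curve of the linear base mechanism
($\beta = 0.2$, $\sigma^2_{X|C} = 50$, $\tau^2 = 30$) the quadratic
extrapolation returns 0.1733 — strictly between the naive 0.125 and the
truth 0.2. That residual under-correction, visible before any sampling
noise enters, is the mechanism behind SIMEX's negative bias at low
reliability, and it shrinks as reliability grows because the curve flattens.
`simex_extrapolate()` with `extrapolant = "linear"` under-corrects even
more; it is kept for diagnostics only. A quartic extrapolant is a known
refinement and deliberately out of scope here.

## The synthetic data generators

Two mechanisms, designed so that every analytic quantity is known in closed
form, drive all testing and the simulation engine.

**Linear (blood pressure and kidney function).**
$\mathrm{Age} \sim N(32, 25)$,
$BP \mid \mathrm{Age} \sim N(120 + \gamma\,\mathrm{Age},\, 50)$,
replicates $BP^* \mid BP \sim N(BP, \tau^2)$, and
$\mathrm{Creatinine} \mid BP, \mathrm{Age} \sim
N(30 + 0.2\,BP + 0.2\,\mathrm{Age},\, \sigma^2)$. The estimand is the
conditional slope 0.2. Base parameterization: $n = 500$, $k = 3$,
$\tau^2 = 30$, $\sigma^2 = 100$, $\gamma = 0$, giving reliability and
attenuation 0.625.

**Logistic (sodium intake and hypertension).**
$\mathrm{Age} \sim U(18, 80)$,
$Na \mid \mathrm{Age} \sim N(4 + \gamma\,\mathrm{Age},\, 1)$,
replicates $Na^* \mid Na \sim N(Na, \tau^2)$, and hypertension Bernoulli
with log-odds $-7 + 0.1\,Na + \phi\,\mathrm{Age}$. The estimand is the
conditional log-odds coefficient 0.1. Base: $n = 4000$, $k = 2$,
$\tau^2 = 2$, $\phi = 0.1$, $\gamma = 0$, reliability 0.33.

`scenario_grid()` returns the full one-factor-at-a-time design for each
family: the base plus 8 error-variance, 4 sample-size, 3 replicate-count,
3 residual-variance (linear) or age-effect (logistic), and 3
covariate-dependency variations — 22 scenarios per family. The
covariate-dependency scenarios are the instructive ones: raising $\gamma$
inflates the marginal exposure variance, so reliability climbs toward 0.98,
yet $\sigma^2_{X|C}$ is untouched and the naive bias stays frozen at
$-(1 - 0.625) = -37.5\%$. Percentage bias equals $-(1 - \text{reliability})
\times 100$ only when exposure and covariates are independent.

Two bookkeeping quirks are worth recording. First, the linear outcome
model's $R^2$ can be computed from the generating coefficients (explained
variance 3 at $\gamma = 0$, so $R^2 = 0.03$ at $\sigma^2 = 100$) or from a
fixed explained variance of 30 (so $\sigma^2 = 20, 5, 10$ maps to
$R^2 = 0.6, 0.86, 0.75$); the two conventions disagree, so
`outcome_r_squared()` exposes both and scenarios are labeled by their
$\sigma^2$ value. Second, the marginal variance of the logistic exposure
uses $\mathrm{Var}(U(18, 80)) = (80-18)^2/12$, which reproduces the
covariate-dependency reliabilities 0.34, 0.68, 0.87.

What the generators deliberately do *not* emulate: skewed or heavy-tailed
error, systematic or differential error, heteroscedastic error,
within-visit correlation between replicates (replicates are i.i.d. given
the truth), missing data, or more than one covariate. Passing tests
therefore certify behavior under classical, normal, homoscedastic error
with a correctly specified outcome model — the regime where RC's
unbiasedness is a theorem rather than an approximation.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `zeta_grid` | 0.5, 1, 1.5, 2 | multiples of $\tau^2$ | the customary SIMEX ladder; $\zeta = 0$ always joins the fit, since a quadratic through only four points is nearly saturated |
| `n_sim` | 100 | refits per $\zeta$ | averages enough pseudo-datasets that extrapolation noise is secondary to sampling noise |
| `extrapolant` | quadratic | — | the standard compromise; linear kept for diagnostics |
| `n_boot` | 999 | resamples | percentile intervals; rows resampled whole so replicates and covariates stay together |
| `ci_level` | 0.95 | — | nominal coverage targeted by the simulation engine |
| `re_estimate_tau2` | `TRUE` | — | when $\tau^2$ came from replicates it is re-estimated inside each resample so the interval carries $\tau^2$ uncertainty; a known $\tau^2$ stays fixed |

## Numerical and design choices

* **Degenerate calibration.** If $\hat\tau^2 \ge \hat\sigma^2_{W|C}$ the
  attenuation factor is non-positive and RC is undefined; `rc_correct()`
  raises an error carrying both values rather than clipping, because
  silent truncation would mask exactly the instability regime (reliability
  near the correction's breakdown point) a user must know about.
* **Failure accounting.** SIMEX refits and bootstrap resamples that fail
  are dropped and counted when under 10% of the total, and abort the run
  otherwise; counts surface in the result diagnostics. Sensitivity draws
  that fail are flagged in the output, never dropped.
* **Seeding.** Every stochastic entry point takes a seed. Repetition-level
  seeds derive from the master seed through a fixed integer stream, so any
  single Monte Carlo repetition or bootstrap resample is reproducible in
  isolation and runs are bit-identical across invocations.
* **Quantiles.** Bootstrap percentile bounds and study-level medians/IQRs
  use linear interpolation between order statistics (R's default type 7).
* **Wald intervals** for the naive fit use normal quantiles for both
  families, matching how the corrected intervals are formed.
* **Nagelkerke pseudo-$R^2$** summarizes the logistic outcome model's
  explanatory strength ($\approx 0.4$ in the base mechanism, computed on
  the true exposure).

## The sensitivity-analysis framework

Without replicates, correction proceeds as quantitative bias analysis in
five steps, each mapped to one operation: (1) quantify the error variance
and its uncertainty (an `error_model` or elicited range); (2) specify its
distribution — `tau_prior()` supports point, uniform, triangular and
trapezoidal shapes, sampled by inverse CDF; (3) correct repeatedly —
`run_sensitivity()` applies RC or SIMEX per draw with that $\tau^2$ treated
as known; (4) visualize — `plot()` on the result shows corrected estimates
against drawn $\tau^2$; (5) conclude from the spread. With RC the corrected
estimate is a deterministic, strictly increasing function of the drawn
$\tau^2$ (for a positive naive estimate), so the prior's spread maps
cleanly onto the estimate's spread. With SIMEX each draw re-runs a
stochastic algorithm (each draw gets its own RNG stream, so the scatter is
genuine SIMEX noise, not seed reuse), and that sampling variability can
exceed the variability induced by the prior — a practical argument for
preferring RC in sensitivity analyses. `probabilistic_bias_summary()`
additionally convolves each draw with a normal sampling distribution
(mean the point estimate, SD its bootstrap SE) and reports pooled
percentiles — the probabilistic bias analysis variant; per-draw bootstrap
is optional because it dominates cost inside a prior loop.

## Problem sizes

The test suite and the acceptance script reproduce the Monte Carlo results
at desk scale — typically 300–2000 repetitions per scenario (5000 for the
small-sample logistic RC bias, whose Monte Carlo standard error is largest),
bootstrap coverage checks at 100–150 repetitions with 149–999 resamples,
and study-level medians over the 42 non-heavy grid scenarios at 20–50
repetitions each. One scale-down is deliberately avoided: coverage checks
keep SIMEX's `n_sim` at its default 100, because a noisier extrapolation
widens the bootstrap intervals and would hide the undercoverage being
measured. Monte Carlo standard errors are reported with
every metric, and stochastic assertions are framed in units of those MCSEs,
so the conclusions do not depend on the chosen repetition counts. The
$n = 10{,}000$ scenarios are in the grid but opt-in (`--include-heavy`),
since they dominate runtime without changing any qualitative conclusion.

## Known limitations

* Logistic RC and the attenuation approximation are first-order; for large
  exposure effects or error variance both degrade (the known small-sample
  positive bias of logistic RC at $n = 500$, and its breakdown at
  reliability $\le 0.2$, are visible in the simulation engine's output).
* Only one error-prone exposure is supported; covariates are assumed
  error-free, and their coefficients are not corrected.
* No survival or Poisson outcome models; no misclassification-SIMEX for
  categorical exposures; no Bayesian bias analysis.
* Bootstrap intervals are percentile-only — no BCa or studentized variants.
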