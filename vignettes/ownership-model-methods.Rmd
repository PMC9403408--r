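---
title: "Methods: a spatiotemporal model of state-level firearm ownership"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a spatiotemporal model of state-level firearm ownership}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firearmsdm)
```

## The estimation problem

State-level firearm ownership in the United States is observed directly only
through surveys: annually at best, each October, and with respondent counts
that drop to single digits in small states. Two administrative proxies are
observed monthly and completely — background checks per capita (`X1`) and
the fraction of suicides committed with a firearm (`X2`) — but neither is
ownership. The package treats ownership `Y` as a latent monthly panel tied
to the proxies through a linear spatial model, calibrated on the October
anchors and then iterated monthly.

## Model

For `n` spatial units and month `m`:

$$Y_m = \rho W_m Y_m + \tau Y_{m-12} + \eta W_m Y_{m-12}
  + \phi^{(1,H)} X^{(1,H)}_{m-1} + \phi^{(1,L)} X^{(1,L)}_{m-1}
  + \phi^{(2,H)} X^{(2,H)}_{m-1} + \phi^{(2,L)} X^{(2,L)}_{m-1}
  + \psi^{(1)} W X^{(1)}_{m-1} + \psi^{(2)} W X^{(2)}_{m-1}
  + \gamma d + \alpha^H i^H + \alpha^L i^L + \varepsilon_m$$

with $\varepsilon_m \sim N(0, \sigma^2 I)$. Assumptions worth making
explicit:

* **Linearity, unbounded response.** Ownership is a fraction, but the model
  is linear and its output is *not* clipped to $[0,1]$: clipping inside the
  recursion would break the Gaussian likelihood. Display-time clipping is
  the user's choice.
* **Twelve-month memory only.** The own-lag and spatial lag act at 12
  months, matching the annual anchor cadence; no shorter memory is modeled.
* **Yearly weights.** Populations are annual, so $W_m$ is constant within a
  calendar year.
* **Response-class split.** Units whose survey respondent count exceeds 10
  in *every* year are high-response (`H`); all others are `L`. Exactly 10
  in some year is `L` — the strict reading of "more than 10 across all
  years"; the threshold is an argument of `classify_response()`. The split
  gives sparsely surveyed units their own proxy slopes and intercept so a
  lone respondent reporting 0 or 1 does not drag the common coefficients.
* **Spatial lag pairing.** The spatial proxy terms pair each lagged proxy
  with the weight matrix of the proxy's own month. Since `W` is constant
  within a year this matters only across January boundaries, and not at all
  in the October-stacked calibration (September and October share a year).

### Parameters

| term | meaning | units |
|---|---|---|
| `rho` | contemporaneous spatial autoregression | – |
| `tau`, `eta` | 12-month own / spatial memory | – |
| `phi1_H`, `phi1_L` | checks-per-capita slope (H / L units) | per check·person⁻¹·month⁻¹ |
| `phi2_H`, `phi2_L` | suicide-fraction slope (H / L) | – |
| `psi1`, `psi2` | spatially lagged proxy slopes (unsplit) | as above |
| `gamma` | linear year trend | per year |
| `alpha_H`, `alpha_L` | class intercepts | – |
| `sigma2` | monthly noise variance | – |

The year dummy `d` is coded 0, 1, 2, … from the first modeled year; any
other origin is absorbed by the intercepts.

## Weight matrix

`build_population_distance_W()` sets
$(W)_{ij} = p_j / (K_i D_{ij})$ with $K_i$ the row-normalizing sum, zero
diagonal: nearer and more populous neighbors weigh more, every row sums
to 1, and the matrix is invariant to rescaling all populations or all
distances. Distances are great-circle (haversine, Earth radius 6371 km);
the builder also accepts a precomputed distance matrix, and
`build_custom_W()` row-normalizes any user kernel (area, GDP, borders, …).
`null_W()` gives the no-interaction benchmark `W = 0`, under which the
model collapses to an ordinary distributed-lag regression.

`rho` must keep $I - \rho W$ nonsingular; the admissible interval is
$(1/\min\omega,\ 1/\max\omega)$ over the real eigenvalues $\omega$ of the
weight matrices (upper bound 1 for row-stochastic `W`).

## Calibration

Ownership is observed only each October, so the monthly model is evaluated
at Octobers and stacked: targets are Octobers of years 2…T, the 12-month
lag is the previous October's *survey* vector, proxies enter at September
of the target year, giving $N = (T-1)n$ rows and 11 regressors in the
fixed column order `Y_L, WY_L, X1_H, X1_L, X2_H, X2_L, WX1, WX2, d, i_H,
i_L`.

`fit_sdm()` follows the standard concentrated-likelihood route: for a
candidate $\rho$, $\hat\delta(\rho)$ is the least-squares fit of
$Y - \rho W Y$ on $Z$ and $\hat\sigma^2(\rho) = e'e/N$; Brent search
(`stats::optimize`, tolerance $10^{-8}$) maximizes the concentrated
likelihood over 99.95% of the open spectral interval, avoiding the boundary
singularities of the log-determinant. Standard errors come from the inverse
observed information — a finite-difference Hessian of the full
log-likelihood in all 13 scalars at the optimum; `sigma2` gets no
t-statistic (no meaningful zero null). Under `W = 0` the spatial columns
are identically zero: their coefficients are pinned at 0, excluded from the
information matrix, and the rest reduces exactly to OLS (a tested
invariant).

### Log-determinant

$\ln|I-\rho W|$ is computed exactly from the pooled complex eigenvalues of
the per-year blocks (each block is only $n \times n$, so this is the
default at the study scale). `logdet_mc()` provides the Monte-Carlo trace
alternative for large `n`: the truncated series
$-\sum_k \rho^k\,\mathrm{tr}(W^k)/k$ with Gaussian probe vectors. Two
refinements matter numerically: the component of each trace along the
constant vector — the Perron direction of a row-stochastic matrix, which
dominates both the value and the probe variance — is computed exactly by
power iteration and removed from the probed space, and the first two traces
are computed exactly at $O(n^2)$. With 100 draws and order 50 the estimator
sits well within 1% of the dense value on matrices up to $n = 20$ (a tested
property); plain undeflated probing misses that by an order of magnitude.

## Anchored monthly prediction

`predict_monthly()` iterates the calibrated model with $\sigma^2 = 0$, so
the trajectory is the conditional mean. The 12 months before the first
modeled year (the burn-in) are filled with the first survey year's values.
To stop a 240-month recursion from drifting, each October's 12-month lag is
replaced by the *previous October's survey values*; all other months lag
the model's own output. A missing anchor falls back to the model value with
a warning and is recorded in `anchors_used`. Fit against the anchors is
summarized by the sum and mean of squared October errors
(`evaluate_fit()`); with a correctly specified model the MSE sits at the
noise floor $\sigma^2$.

The national series is *not* an average of state outputs: national proxies
are rebuilt by aggregating counts (the panel stores rates and fractions, so
counts are reconstructed as rate × population — an approximation for the
suicide fraction, whose true denominator is total suicides, not
population), and the model is iterated on the single national series with
`n = 1`, all spatial terms zero, and high-response coefficients.

## Preprocessing for causal analysis

* **Seasonal adjustment** is a classical additive decomposition
  (`stats::decompose`): centered 2×12 moving-average trend, month-mean
  seasonal factors centered to sum to zero, removed additively. This is a
  deliberate, testable substitute for ARIMA-model-based signal extraction:
  the causal stage only needs the period-12 component gone, and the
  classical estimator annihilates a pure sinusoid to machine precision.
  Outlier handling and calendar effects are out of scope.
* **Detrending** subtracts the OLS line on the time index.
* **Stationarity** is checked by an augmented Dickey–Fuller regression with
  constant and no trend, lag order 0…12 chosen by AIC, against MacKinnon
  (2010) response-surface 5% critical values.
* **Symbolization**: continuous series map to `1` when the next value is
  strictly greater, else `0` (ties → 0); event counts map to `1` when at
  least one event occurred. Change symbolization is invariant under any
  strictly increasing transform. Change-rule output is one shorter than its
  input, so a triad is truncated to the common length — event series lose
  their final element.

In a standard triad (model output, event counts, media volume) the model
output is adjusted + detrended + change-symbolized, events are
event-symbolized, and the media series is change-symbolized without
adjustment.

## Conditional transfer entropy and the permutation test

With binary symbols and a first-order embedding at unit time step,
$TE_{Y\to X|Z} = H(X_{t+1}|X_t,Z_t) - H(X_{t+1}|X_t,Y_t,Z_t)$ is computed
by plug-in frequencies over the 16 joint states of
$(X_{t+1}, X_t, Y_{t-\ell}, Z_{t-\ell})$; $\ell = 0$ is the main analysis
and $\ell = 1\ldots11$ the delay analysis (source and conditioner are
lagged together). No bias correction is applied to the estimator — the
permutation null absorbs the plug-in bias.

Significance uses a *local* permutation scheme: time points are stratified
by the realized pair $(X_t, Z_t)$ — four cells — and the source symbols are
shuffled only within each stratum, so every surrogate preserves the
conditional structure (an empty stratum is left untouched; this is also
why a source that is a deterministic function of the stratum yields p = 1,
a tested property). The p-value is the right-tail fraction
$(1 + \#\{TE^{surr} \ge TE^{obs}\}) / (1 + n_{perm})$: ties count toward
the tail and the +1 keeps p strictly positive — marginally conservative,
preferred to reporting p = 0. The default is 50 000 surrogates with
significance when the observed value exceeds the surrogate 95th percentile;
tests and the acceptance script use 1 000–2 000 surrogates, which is ample
for calibration checks.

## Synthetic data: what it emulates, and what it does not

`generate_scenario()` produces the study conditions end to end: 48 units,
20 years of monthly proxies (11 520 cells per proxy), October anchors
(960), 8 low-response units with annual respondent counts of 1–12
(guaranteeing at least one sub-threshold year, and producing the degenerate
0/1 anchors a single respondent forces under binomial sampling), and
event/media series over the same calendar. Generating parameters default to
the calibrated operating point (`rho = 0.163`, `sigma2 = 0.031`, proxy
coefficients of the reported magnitudes).

Scenario levels were fixed once at realistic magnitudes: mean checks per
capita 0.004/month with a 35% winter-peaking seasonal swing (the
2000–2019 national average magnitude and its pronounced seasonality), and
a suicide firearm fraction of 0.58 with a slow negative drift. Under the
default coefficients these levels put simulated ownership near 0.5, so
truncating survey fractions to $[0,1]$ touches only ~1% of anchor cells.
Survey noise is binomial(respondents, ownership)/respondents — the natural
sampling model for a survey fraction — with an exact option for
self-consistency tests. The burn-in `Y_init` is the fixed point of the
first October map, so a noiseless simulation reproduces its own anchors
exactly and the anchored predictor replays the simulation to $10^{-10}$ (a
tested invariant).

What the generator does **not** emulate: real geography (centroids are a
jittered grid), survey design effects beyond binomial sampling, policy
shocks or structural breaks in the proxies, and cross-proxy feedback.
Passing tests therefore demonstrate internal consistency and estimator
correctness under the model's own assumptions — not that the model is a
faithful description of any real administrative series.

`generate_coupled_triad()` supplies the causal test-bench: independent
triads, a lag-1 copy coupling of chosen strength (analytic TE
$1 - H_b((1+s)/2)$, one full bit at strength 1), and a two-step chain with
a persistent source whose pairwise link is spurious and disappears under
conditioning.

## Numerical choices and edge cases

* Duplicate centroids (zero distance) are an error, not a silent `Inf`.
* `rho` at or beyond a spectral bound raises an error naming the bound.
* Constant series are rejected by the ADF check (degenerate regression).
* Result JSON is written at 17 significant digits so `read_results()`
  round-trips doubles bit-exactly.
* All stochastic components (simulation noise, survey sampling, probe
  vectors, permutations) are seeded; identical seeds give bit-identical
  outputs.

## Known limitations

* Under the default conditions $\hat\rho$ shows a modest downward
  finite-sample bias (about half a reported standard error at
  $n = 48, T = 20$): the spatially lagged response varies little across
  units once the proxy columns are partialled out, a weak-identification
  regime in which spatial ML is known to be biased toward zero.
  Three-standard-error coverage of all coefficients still exceeds 90% over
  100 replicates (a tested property). Recovery studies should compare
  against the reported standard errors, not expect point equality.
* The national suicide-fraction aggregation weights by population rather
  than by suicide counts, which the panel does not carry.
* Significance in a six-link triad table is per-link at
  $\alpha = 0.05$; no multiplicity correction is applied, matching the
  table convention it mirrors.

## Scales used by the test-suite

Property tests run at reduced but informative sizes chosen for sharp
oracles: exact identities on toy panels (n = 2–8), a 100-replicate recovery
study at the full study scale (n = 48, T = 20), permutation calibration on
500 null triads of length 216 at 2 000 surrogates, and power on 100 coupled
triads. The acceptance script repeats the same computations at 50/200/50
replicates and finishes in about a minute on one CPU.
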