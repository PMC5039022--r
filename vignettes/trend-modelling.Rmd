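---
title: "Semiparametric trend modelling for aerial strip-transect surveys"
author: "srftrends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semiparametric trend modelling for aerial strip-transect surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srftrends)
```

## The monitoring problem

Rangeland wildlife and livestock in East Africa are monitored by systematic
reconnaissance flights (SRF): an aircraft flies parallel transects at fixed
spacing and observers count animals inside calibrated strips.  The counting
unit is a grid cell, typically 5 km x 5 km, of which only the strip is
actually searched, so each sampled unit contributes a count `y` and a
sampled area `z`.  Counties are surveyed in different, irregular years, with
multi-year gaps; counts are strongly overdispersed; and most management
questions are about decade-scale change: how much has each species declined
or increased between an early baseline and today, county by county and
summed over the whole rangeland system?

`srftrends` implements that analysis chain end to end: design-based
abundance estimation per survey, a multivariate semiparametric
negative-binomial mixed model for the resulting time series, prediction of
unsurveyed years, aggregation to regional series, period averages,
percentage changes and biomass summaries, and regressions of density on
anthropogenic and climatic covariates.  A synthetic-data generator with the
same statistical structure makes every stage testable without field data.

## Design-based estimation: Jolly's Method 2

For transects (units) of unequal length the ratio estimator is

\[
\hat R = \frac{\sum y_i}{\sum z_i}, \qquad \hat Y = Z \hat R,
\]

with `Z` the zone (county) area, and the finite-population-corrected
variance

\[
\widehat{\mathrm{Var}}(\hat Y) = \frac{N(N-n)}{n}
  \left(s_y^2 - 2\hat R s_{zy} + \hat R^2 s_z^2\right),
\]

where `N` is the number of units in the zone, `n` the number sampled, and
the sample moments use `n - 1` denominators (the Jolly 1969 convention; the
choice matters only in small samples and is stated here because different
texts write the moments without denominators).  Two consequences worth
knowing: the variance is exactly zero when counts are proportional to areas
(the ratio model is then exact) and when `n = N` (a census); and because
\(s_y^2 - 2\hat R s_{zy} + \hat R^2 s_z^2\) is the sample variance of
\(y_i - \hat R z_i\), the estimate can never be negative, so the defensive
clamp in the code is never expected to fire.

## The trend model

Let \(Y_{sj}\) be the population estimate of species `s` at survey date
\(t_j\) in one county.  The model is a negative-binomial (NB2) mixed model
on the log scale:

\[
Y_{sj} \sim \mathrm{NB}(\mu_{sj}, k), \qquad
\mathrm{Var}(Y) = \mu(1 + \mu/k),
\]
\[
\log \mu_{sj} = \beta_s + \gamma_s (t_j - \bar t)
  + s_1(t_j) + s_{2,s}(t_j) + \log \bar Y_s ,
\]

with species intercepts \(\beta_s\), species linear time slopes
\(\gamma_s\), a smooth trend \(s_1\) common to all species, a smooth trend
\(s_{2,s}\) specific to each species, and the log of the species' mean
estimate as an offset, so intercepts measure departures from the species'
own average and species of very different abundance can share one model.

Both smooths are penalized cubic B-splines (P-splines): a basis of degree
`d = 3` on `m = 20` equally spaced interior knots (boundary knots at full
multiplicity, giving `K = m + d + 1 = 24` basis columns and a partition of
unity on the survey window), with a third-order difference penalty
(`r = 3`) on adjacent coefficients.  The penalized fit is computed in its
mixed-model form: with `U` the basis matrix and `Q` the `(K - r) x K`
difference matrix,

\[
Z = U (Q^\top Q)^{-} Q^\top = U Q^\top (Q Q^\top)^{-1},
\]

and the spline coefficients become `ds1 = K - r = 21` i.i.d. random effects
with variance \(\sigma^2_{u1}\) (common trend) and `ds1 x p` block-diagonal
random effects with variance \(\sigma^2_{u2}\) (species-specific trends).
The smoothing parameters are then just variance-component ratios and are
estimated automatically.  For `p = 12` species on a calendar of 34 surveys
plus 11 unsurveyed years this gives the bookkeeping the package's tests pin
down: a 540-row observation grid, a `540 x 24` fixed design, `ds2 = 252`
species-specific columns and `21 + 252 = 273` random coefficients in total.

### Why the linear time slopes are fixed effects

The reparameterized design `Z` spans only the orthogonal complement of the
penalty null space: coefficient vectors that are polynomials of degree
`r - 1` in the knot index are annihilated by `Q` and therefore cannot be
produced by any `u`.  A smooth log-linear trend — exactly what an
exponentially declining population generates — lives essentially in that
null space.  Numerically, projecting a 63% log-linear decline onto the
span of intercept-plus-`Z` recovers barely half the decline, and REML
correctly responds by shrinking both spline variances to zero, leaving a
flat fit.  The unpenalized polynomial part of a P-spline smoother must
therefore enter as fixed effects.  The package includes per-species linear
slopes by default (`fixed_species_slopes = TRUE`, the `q = p` interaction
columns of the `540 x 24` design above); the quadratic null-space direction
is left out to match the model dimensions above, which costs some
flexibility for strongly curved trends but is harmless for the
exponential-type trajectories the model targets.  Setting
`fixed_species_slopes = FALSE` reproduces the intercepts-only variant.

### Fitting by penalized quasi-likelihood

`sglmm()` alternates three steps until the maximum relative change over all
parameters falls below `1e-6` (default cap 2000 iterations; failure to
converge is an error carrying the full iteration trace):

1. **Working linear mixed model.**  With \(\eta\) the current linear
   predictor and \(\mu = e^\eta\), form the working variate
   \(e = (\eta - \mathrm{offset}) + (y - \mu)/\mu\) and weights
   \(w = \mu / (1 + \mu/k)\), and solve Henderson's mixed-model equations
   for \((\beta, u)\) with ridge terms \(1/\sigma^2_{u1}\),
   \(1/\sigma^2_{u2}\) on the two random blocks.
2. **Variance components.**  Schall-type REML fixed point:
   \(\sigma_j^2 \leftarrow \|u_j\|^2 / \nu_j\) with
   \(\nu_j = q_j - \mathrm{tr}(C^{-1}_{jj})/\sigma_j^2\) the effective
   degrees of freedom of block `j` (`C` the mixed-model coefficient
   matrix).  Components falling below `1e-6` — negligible on the log-link
   scale, where the linear predictor is O(1) — are snapped to the `1e-10`
   clamp rather than being allowed to decay geometrically forever; the
   event is recorded in the fit.
3. **NB shape.**  Pearson moment matching: `k` solves
   \(\sum (y_i-\mu_i)^2 / \{\mu_i(1 + \mu_i/k)\} = n - \mathrm{edf}\)
   (via `MASS::theta.mm`), with `edf` the current effective model
   dimension.  Exactly three variance components are estimated:
   \(\sigma^2_{u1}, \sigma^2_{u2}, k\).

Initialization: \(\eta_0 = \log(y + 0.5)\), intercepts by least squares of
\(\eta_0 - \mathrm{offset}\), `u = 0`, variances 0.1, `k = 1`.  The
penalized working-model objective is monitored and violations of
monotonicity are counted in the fit object.  The response is the Jolly
estimate rounded to the nearest integer (raw values are kept for
plotting); estimates' own standard errors are *not* propagated into the
trend likelihood — a known limitation shared with the modelling tradition
this follows.  When both variances are forced to zero the algorithm is
ordinary IRLS, and its intercepts agree with `MASS::glm.nb` to 1e-6, which
the test suite uses as an oracle.

### Prediction

`predict()` returns \(\exp(\hat\eta)\) with the pointwise band
\(\exp(\hat\eta \pm 1.96\,\mathrm{SE}(\hat\eta))\), the SE taken from the
joint PQL covariance of \((\hat\beta, \hat u - u)\) at convergence.  Years
with surveys are predicted at their actual survey dates; years without are
assigned mid-June (decimal year + 0.45).  Extrapolation outside the spline
window is refused.  In simulations with dense data the band's pointwise
coverage of the true trajectory is close to nominal (the suite checks
90-99% over 200 replicates).

## Aggregation conventions

* Multiple surveys in a calendar year are fitted as separate observations
  and averaged *after* fitting (`annualize()`).
* Regional ("national") totals are sums over counties with every county
  contributing — a missing county-year is an error, never a silent zero;
  unsurveyed years must first be filled by model predictions.
* Period averages default to the baseline 1977-1980 and comparison periods
  1994-1997 and 2011-2013, with optional per-county end-year overrides
  (e.g. extending to 2014-2016 where later surveys exist);
  `baseline_1978 = TRUE` in `run_config()` reproduces the alternative
  1978-1980 baseline.  Percent change is baseline-referenced,
  `100 (b - a)/a`, computed on unrounded values and reported at one
  decimal; it is deliberately asymmetric in its arguments.
* Biomass is count x unit weight (kg/animal).  The shipped
  `default_unit_weights()` table is illustrative only — real analyses
  should supply their own weights — and `biomass_rollup()` refuses species
  without a weight rather than guessing.

## Covariate analyses

* **Census interpolation**: between census anchors, population follows
  \(P(t) = p_1 e^{r(t-t_1)}\) with \(r = \ln(p_2/p_1)/(t_2-t_1)\) — exact
  at the anchors and multiplicatively consistent across chained anchors.
* **Climate trends**: the test of a monotone temperature or rainfall trend
  is OLS on calendar year with a two-sided t-test; this is the simplest
  test consistent with the reported analyses, and its type-I error is
  verified by simulation in the suite.
* **Density-covariate curves**: NB regression with log link and
  `log(county area)` offset; AICc chooses between linear and quadratic
  forms, counting the NB shape among the parameters
  (\(AICc = -2\ell + 2q + 2q(q+1)/(n-q-1)\)).  For a concave quadratic the
  density peaks at \(-\beta/2\gamma\); a negative peak is reported at 0
  (avoidance), and \(\gamma \ge 0\) is reported as monotone, not an error.
  No random term is included by default because no grouping structure is
  implied at county-year granularity.
* **Constant-variance curves**: where NB bands are uninformatively wide,
  an exponential-quadratic mean \(y = \exp(b_0 + b_1 x + b_2 x^2)\) is fit
  by homoscedastic least squares (`nls`, port algorithm, log-linear least
  squares start).  The functional form mirrors the NB mean curve so the
  two fits are comparable; this choice is the package's own, as the
  constant-variance model's mean function is otherwise unconstrained.
* **Forward selection under strong hierarchy**: candidates are the
  centered-and-scaled main effects, their squares and all pairwise
  interactions; a square or interaction becomes eligible only when all its
  constituent mains are in the model.  At each step the eligible effect
  with the largest improvement of the chosen criterion (AICc, AIC or BIC)
  enters; ties break by improvement then alphabetically, making selection
  deterministic.  Final coefficients are reported back on the original
  covariate scale.

## What the synthetic generator does and does not emulate

`scenario_config()` reproduces the statistical structure the analysis
assumes: 5 x 5 km sampling units (with a configurable coefficient of
variation for unequal transect lengths), a sampling fraction defaulting to
the historical 5.7% coverage, NB2 unit- and estimate-level counts with
shape `k` (default 2, strongly overdispersed), irregular survey calendars
with multi-year gaps, species trajectories that are flat, exponential
(default wildlife decline 2.88%/yr, about 68% over 39 years) or logistic
(rising shoats), exponential human population growth through census anchor
years (mean rate 3.35%/yr, matching a 4.8-fold rise over 47 years), linear
warming (default 0.02 deg C/yr, within the observed 0.7-1.9 deg C over 54
years) and weakly declining, noisy rainfall.  All randomness derives from
one master seed through named substreams, so any stage can be regenerated
independently and byte-identically.

It deliberately does **not** emulate: spatially explicit animal
distributions within counties, rainfall quasi-periodicity, or seasonal
migratory/resident population switching (each species-county is a single
population; season-split analyses are supported by running the pipeline on
pre-partitioned input).  Passing tests therefore demonstrate correctness of
the estimators and fitting machinery under the stated generating model, not
robustness to spatial aggregation or migratory double-counting in real
surveys.

## Numerical choices and problem sizes

Simulation-based tests use one county with four species on the default
40-year calendar (28 surveys) for trend-recovery checks (200 replicates),
two species with `k = 10^4` and annual surveys for band-coverage checks
(200 replicates), and 200-500 replicates for the regression and selection
simulations — sizes chosen to make Monte-Carlo error small relative to the
assertion margins while keeping the default test run brief.  Degenerate
inputs are handled explicitly rather than incidentally: single-unit
surveys return an estimate with undefined SE, species with all-zero
estimates are excluded from the trend fit (their offset would be
\(-\infty\)) with a message, constant covariates are rejected as
unidentifiable, and a flat response short-circuits the nonlinear fit to
its closed-form solution.

## Known limitations

* PQL is approximate; its bias is largest for small counts with heavy
  overdispersion.  The recovery simulations quantify the net effect under
  the default scenario (mean recovered decline within ~3 points of truth).
* Jolly standard errors are not propagated into the trend model.
* The quadratic penalty null-space direction is not in the fixed design
  (see above); strongly U-shaped log-trends will be partially attenuated.
* The radial-basis fallback smoother with k-d-tree knots used elsewhere
  for non-converging counties is out of scope here; the P-spline smoother
  with the Schall update converged in all tested scenarios.
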