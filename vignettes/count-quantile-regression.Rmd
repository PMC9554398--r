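---
title: "Quantile regression for counts: jittering and coefficient modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantile regression for counts: jittering and coefficient modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(countqr)
```

## The problem

Counts with irregular distributions — the motivating example is the number of
ECTS credits earned by first-year university students in one semester,
divided by 3 so the support is roughly $\{0,\dots,21\}$ — are poorly served
by conditional-mean models, and standard quantile regression cannot be
applied directly either: the pinball objective is non-differentiable and the
response is discrete, which breaks the usual asymptotics and can create
identification problems. `countqr` implements the two estimators that make
quantile regression work for counts, on a common data container and with a
common recovery rule for count quantiles, so they can be compared on equal
terms.

Throughout, $y_i$ is a count, $x_i$ a covariate vector with leading 1, $q$
the number of covariates, and $p \in (0,1)$ the quantile order. Single-level
quantile regression minimises

$$L(\beta(p)) = \sum_{i=1}^n \big(p - \omega_{p,i}\big)\big(t_i - x_i'\beta(p)\big),
\qquad \omega_{p,i} = I\big(t_i \le x_i'\beta(p)\big),$$

over $\beta(p)$, where $t_i$ is a transform of the (working) response. Every
summand is non-negative.

## Estimator 1: average jittering

Jittering replaces the count by the continuous working variable
$Z = Y + U$, $U \sim \mathrm{Uniform}[0,1)$, whose conditional quantiles are
in one-to-one correspondence with those of $Y$. Quantile regression is fitted
to a monotone transform $T(Z; p)$; the count quantile is recovered by

$$\hat Q_Y(p \mid x) = \lceil T^{-1}(x'\hat\beta(p)) - 1 \rceil .$$

Because $\hat\beta(p)$ depends on the realised noise, the estimation is
repeated on $m$ independent jitter draws and averaged:
$\hat\beta^A_m(p) = m^{-1}\sum_l \hat\beta^{(l)}(p)$.

Design choices:

* **Transform.** The default is the linear transform $T(Z,p) = Z - p$
  (subtracting $p$ because the quantile function of $Z$ is bounded below by
  $p$), which keeps coefficients interpretable on the count scale and matches
  the identity-scale QRCM fit it is compared against. The original logarithmic
  transform $\log(Z-p)$ for $Z > p$, $\log\zeta$ otherwise, is available via
  `jitter_config(transform = "log")`; $\zeta$ defaults to $10^{-5}$ — any
  sufficiently small positive constant works, it only affects observations
  with $Z \le p$, which carry no information about the upper branch.
* **One working sample per replication.** The noise is drawn once per
  replication $l$ and reused for every $p$ in the grid, since the averaging
  is indexed by replications, not quantile levels. This also makes the
  coefficient path in $p$ internally consistent within a replication.
* **Bootstrap standard errors.** Nonparametric bootstrap over cases
  (default $B = 100$), with fresh jitter noise inside every resample; the SE
  is the standard deviation of the average-jittering estimate across
  resamples. Whether the noise should be redrawn inside resamples is not
  settled; we re-jitter, which charges the estimator for its jitter noise
  and is therefore the conservative choice. The `m_boot` replication count
  inside each resample defaults to 20: resampling noise dominates well
  before jitter noise at that point, at a fifth of the cost of the full
  `m = 100`.
* **Negative recovered quantiles** under the linear transform are reported
  as-is, never clamped — with a linear specification small negative
  predictions at extreme quantiles are an expected and informative artefact.

The single-level solver is a Frisch–Newton primal–dual interior-point method
on the dual linear program
$\max\{t'a : X'a = (1-p)X'\mathbf{1},\ a \in [0,1]^n\}$, with Mehrotra
predictor–corrector steps; each iteration costs one $(q+1)\times(q+1)$
solve. The solution of quantile regression is set-valued in general; the
solver returns one minimiser and all package contracts compare achieved
losses, never coefficients. The test suite verifies loss-optimality against
an independent vertex-enumeration oracle to $10^{-6}$ relative.

## Estimator 2: quantile-regression-coefficients modelling (QRCM)

Instead of fitting each quantile separately, every coefficient is a
parametric curve in $p$,

$$\beta(p \mid \theta) = \theta\, b(p), \qquad
\beta_c(p \mid \theta) = \theta_{c1} b_1(p) + \dots + \theta_{ck} b_k(p),$$

with known basis functions $b(p)$ and a $(q+1)\times k$ parameter matrix
$\theta$ in which entries can be fixed at zero (the sparsity mask of
`model_spec()`). All free parameters are estimated jointly by minimising the
integrated loss

$$\bar L(\theta) = \int_0^1 L(\beta(p \mid \theta))\,\mathrm{d}p ,$$

which is smooth enough in $\theta$ for standard optimisation and
M-estimation theory. For a count response the model is fitted to the offset
working response $y^\circ = y + 0.5$ — the expectation of the jittered
variable — rather than to a random jitter draw; the parametric structure
smooths the mass points away, and fits to $Z$ and to $y^\circ$ agree to a
fraction of a standard error for all but the most step-sensitive parameters
(see the test suite).

### Basis functions

Polynomial terms use *shifted Legendre polynomials*, orthogonal on $[0,1]$
($1$, $2p-1$, $6p^2-6p+1$, ...): they span the same space as raw monomials
and return the same fit, but keep the optimisation well conditioned.
`legendre_shifted_coeffs()` exposes the monomial coefficients for reporting.
$-\log(1-p)$ (and $\log p$, $p^{1/k}$) are available for tail behaviour;
$-\log(1-p)$ lets a coefficient grow without bound as $p \to 1$, the natural
shape for a right tail with no fixed upper bound.

### Numerical choices

* **Quadrature.** $\bar L$ and its gradient are evaluated with a fixed
  199-node Gauss–Legendre rule mapped to $(0,1)$. The nodes are strictly
  interior, so $-\log(1-p)$ stays finite; 199 nodes reproduce the pointwise
  pinball objective to full precision and refining to 999 nodes changes
  $\bar L$ by under $10^{-4}$ relative (both are asserted in the tests).
* **Optimiser.** The quadrature loss is convex and piecewise linear in
  $\theta$. The free parameters are updated by Newton steps with the
  closed-form curvature described below and Armijo backtracking; BFGS with
  the analytic (almost-everywhere) gradient is the fallback when Newton
  stalls away from a stationary point. The gradient ignores the dependence
  of the indicators on $\theta$, which is valid almost everywhere.
* **Initialisation.** The constant-basis column starts at the
  single-quantile median fit, and the linear column at the interquartile
  spread of single-quantile fits — a flat starting curve has no usable
  curvature. Fits are deterministic given data and starting point.
* **Monotonicity** of the fitted quantile function is not enforced (the
  estimator is defined without that constraint); violations over the node
  grid at observed covariate rows raise a warning.

### Covariance, Wald tests, confidence bands

The sandwich covariance $H^{-1} G H^{-1}$ uses the outer-product matrix $G$
of per-observation integrated gradient contributions and the curvature $H$
of the integrated estimating equation. Because the quadrature loss is
piecewise linear, a finite-difference Hessian would be step-size fragile;
instead $H$ is computed in closed form through the fitted PIT values: with
$p^*_i$ solving $x_i'\theta b(p) = y^\circ_i$,

$$H = \sum_i \frac{[x_i \otimes b(p^*_i)]\,[x_i \otimes b(p^*_i)]'}
{x_i'\theta\, b'(p^*_i)},$$

which is positive semi-definite by construction; observations whose working
response falls outside the fitted quantile range contribute no curvature,
and the local slope (estimated from the node grid) is floored at $10^{-3}$.
In a dedicated simulation the resulting 95% intervals cover the population
minimiser at 94%, i.e. the sandwich is calibrated; coverage of the
*latent-model* parameters is slightly lower because the population minimiser
under the discretised working response is biased by up to $\approx 0.1$ on
high-degree polynomial terms (see Limitations).

`wald_test_global()` tests that all free entries in one covariate's row are
zero with a chi-square quadratic form (one degree of freedom per free
entry). Pointwise 95% confidence bands for $\beta_c(p)$ come from the delta
method on $b(p)'$-combinations of the covariance block.

### Goodness of fit

Under a correctly specified continuous model the PIT values
$F(y_i \mid x_i, \theta)$ are uniform. `pit()` computes them by monotone
root-finding of $x'\beta(p \mid \hat\theta) = y^\circ$ over the node grid
with linear interpolation; for a non-monotone fitted curve the first upward
crossing is used, and values are clamped to $[10^{-4}, 1-10^{-4}]$ (the
clamp only matters for observations outside the fitted range, where the PIT
is not identified anyway). `gof_test()` measures the Kolmogorov–Smirnov or
Cramér–von Mises distance from uniformity and computes a Monte Carlo
p-value by parametric bootstrap: each replicate draws $p \sim U(0,1)$, sets
$y^\circ = x'\beta(p \mid \hat\theta)$ — the *continuous working model*, on
which the test is defined — refits the model, and recomputes the statistic.
Refitting per replicate (rather than fixing $\hat\theta$) is the more
conservative choice and accounts for estimation noise in the observed
statistic. For a discrete response the PIT is only approximately uniform,
so on real counts the test should be read as a diagnostic, not an exact
test; its size under the continuous working model is verified by simulation
in the test suite (rejection rate at the 5% level within $[0.01, 0.12]$).

## The model grid

`build_candidate_models()` constructs five candidate specifications for the
credits analysis on the eleven-coefficient layout (intercept; standardised
first-semester credits; cohort-2019 dummy; male dummy; standardised
high-school grade; six school-type dummies): a linear-in-$p$ baseline where
every coefficient uses Legendre degrees 0–1 (22 parameters), then four
models in which the intercept and the cohort coefficient are flexible
(Legendre 0–5 or 0–8 plus $-\log(1-p)$), the three continuous/binary
controls are low-order polynomials, and the school-type coefficients are
constants, $\beta_c(p) = \theta_{c0}$ (25, 26, 32, 32 parameters). Keeping
the school-type coefficients constant outside the baseline model is a
deliberate identification choice: with seven small categories,
quantile-dependent school effects would be weakly identified. `poly(p, r)`
always expands to Legendre degrees $0..r$, i.e. $r+1$ terms.

The minimised integrated loss is exported per model (`loss_table()`): it is
non-increasing under nesting — asserted in the tests — but carries no
complexity penalty, and no information criterion exists for this estimator,
so the grid deliberately does **not** auto-select. The intended
model-selection workflow is the overlay diagnostic (`beta2_overlay()`):
QRCM coefficient curves with bands on top of the per-percentile jittering
estimates, with jittering serving as the non-parametric reference. The
reporting defaults to the 26-parameter model, which balances a flexible
effect-of-interest curve against parsimonious controls.

## The synthetic cohort generator

The credits data come from an administrative archive and are not deposited,
so the package ships a generator (`generate_credits_data()`) that emulates
the motivating cohort at the *marginal* level and replaces the unknown truth
with a known one:

* covariate marginals match the cohort's summary characteristics — 79.5% female,
  the seven school-type shares, high-school grade with mean 81.17 and
  SD 11.00 on the 60–100 scale (the latent normal is moment-matched so the
  truncated, integer-rounded variable hits those moments), first-semester
  credits with mean 21.6 / SD 6.64 on positive multiples of 3, cohorts
  balanced;
* covariates are drawn independently — their joint distribution is unknown;
  this is the one structural assumption the generator adds;
* the response is an inverse-transform draw from a known conditional
  quantile function with the selected model's structure: per row
  $p \sim U(0,1)$, $y^\circ = x'\theta_{\mathrm{true}}\,b(p)$,
  $y = \min(\max(\lceil y^\circ - 1\rceil, 0), 21)$. The ceiling mirrors the
  estimators' recovery rule, so the generator's true count quantiles are
  exactly what the estimators target, and the latent $p$ is returned for
  tests.

$\theta_{\mathrm{true}}$ is a synthetic choice, not an estimate from any
real data: the intercept curve spans roughly 8–15 across $p$ (covering the
bulk of the credit-unit support), the cohort curve is mildly negative
with stronger tail effects, control-coefficient slopes are kept small
enough that the quantile function is strictly increasing over every
covariate profile the generator can produce (validated on a profile hull at
construction and on every draw), and school effects are constants between
$-0.18$ and $-0.79$. Under the default configuration the implied median
count for the reference profile is 10 and clamping at $\{0, 21\}$ never
exceeds 1% of draws.

What the generator does **not** emulate — and hence what passing tests do
not show about real credits data: the point mass at zero credits and the
multi-modal spikes of the real distribution (whole exams passed or failed
move the count by 2–4 at once), within-student exam-level structure, and
covariate dependence. The first omission matters for one qualitative
finding: on the real data the jittering estimator is very noisy at low
quantiles (sparse left tail), which is exactly where QRCM's smoothing buys
precision — there the QRCM-to-jittering average-SE ratio is far below one. The
synthetic cohort has a smooth left tail, so there the jittering estimator is
*not* tail-penalised and the measured ratio at $p = 0.10$ is around or
slightly above 1, while the precision gain shows on the steep right tail
instead (ratio $\approx$ 0.66–0.83 at $p = 0.75$–$0.90$ on the default
cohort). The direction of the tail-precision comparison on synthetic data is
therefore a property of the tail the generator produces, not a contradiction
of the method.

## Preprocessing and pipeline

`load_records()`/`preprocess()` implement the case-study preparation:
semester credit totals must be non-negative multiples of 3 (all exams award
6, 9 or 12 credits); students with zero first-semester credits are dropped
(their second-semester exams are mostly first-semester material, and they
are a low-productivity group throughout); the response is second-semester
credits over 3; first-semester credits and grade are centred and divided by
their sample SDs ("scaled" is read as SD-scaling — the scale factor is
otherwise undefined); dummies for cohort 2019 and male; school-type dummies
against the "Scientific" baseline. `run_full_analysis()` chains everything
and writes the report tables as CSV plus a JSON manifest that logs every
derived seed; outputs contain no timestamps and are byte-identical across
reruns with the same seed. The average-SE table averages over all eleven
coefficient rows — the full set is the reproducible choice of averaging
set. A failed stage marks the bundle
partial and names the stage instead of aborting the bundle.

Problem sizes used by the checked-in analyses: the workflow scripts run the
n = 649 cohort with m = 50–100 jitter replications, B = 100 bootstrap
resamples (m_boot = 20) and 100 Monte Carlo goodness-of-fit replicates; the
test suite's recovery and calibration studies use n = 5000 with 50 seeds,
and the goodness-of-fit size study uses 100 datasets of n = 150 with 200
Monte Carlo replicates at a 60-node quadrature. These sizes give
Monte-Carlo error comfortably below the tolerances they are checked
against.

## Known limitations

* Fitting a continuous working model to coarse counts biases the
  *population minimiser* away from the latent truth, concentrated in
  high-degree polynomial coefficients (up to $\approx 0.1$ at the default
  generator's step width). Confidence intervals are calibrated for the
  population minimiser; against the latent truth their pooled coverage is a
  few points below nominal at n = 5000. More support points, or stronger
  continuous covariates, shrink the effect.
* The PIT is only approximately uniform for discrete responses; the
  goodness-of-fit p-value is exact only under the continuous working model.
* Quantile crossing is possible for extreme covariate profiles; the package
  warns rather than constrains.
* The integrated loss compares models of equal complexity only; there is no
  information criterion, and the overlay diagnostic requires judgement.
* The jittering bootstrap treats rows as exchangeable; clustered or
  longitudinal structure is out of scope, as are censored/truncated QRCM
  extensions and spline/trigonometric bases (the basis type accepts
  extensions, but they are not wired into the model grid).
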