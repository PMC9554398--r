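# countqr — quantile regression for count responses

`countqr` is an R package for linear quantile regression when the response
is a count with an irregular distribution. The motivating application is
educational production: the number of ECTS credits earned by first-year
university students in one semester (divided by 3, so the support is about
0–21), analysed to measure the effect of a cohort-level change — emergency
remote teaching — across the whole conditional distribution rather than at
the mean. The audience is applied statisticians who want covariate effects
at the 10th or 90th percentile of a count outcome, with honest uncertainty.

Quantile regression cannot be applied to counts directly: the pinball
objective is non-differentiable and the response is discrete. The package
implements the two standard ways around this, on a shared data container so
they can be compared:

**Average jittering.** Add uniform noise, `Z = Y + U`, `U ~ Uniform[0,1)`;
fit standard quantile regression to a transform `T(Z, p)` (default the
linear `Z - p`) at each quantile order `p`; average the estimates over `m`
independent noise draws; recover count quantiles with the ceiling rule

```
Q_Y(p | x) = ceil( T^{-1}( x' beta(p) ) - 1 ).
```

Standard errors come from a case bootstrap with re-jittering. The
single-level solver is a Frisch–Newton interior-point method written for
this package and verified against an exact vertex-enumeration oracle.

**Quantile-regression-coefficients modelling (QRCM).** Write every
coefficient as a parametric curve in the quantile order,
`beta_c(p | theta) = theta_c1 b_1(p) + ... + theta_ck b_k(p)`, with shifted
Legendre polynomials and `-log(1-p)` as basis functions and zero
restrictions on `theta`, and estimate all parameters jointly by minimising
the integrated pinball loss

```
Lbar(theta) = integral_0^1 L( beta(p | theta) ) dp
```

over a 199-node Gauss–Legendre rule, fitting the offset working response
`y + 0.5`. Inference uses an M-estimation sandwich covariance (global Wald
tests per covariate, pointwise confidence bands), and model fit is checked
by a probability-integral-transform test (Kolmogorov–Smirnov or
Cramér–von Mises) with Monte Carlo p-values from a parametric bootstrap.

The original credits data live in a university administrative archive and
are not public, so the package ships a synthetic cohort generator that
matches the cohort's covariate marginals and draws counts from a known
conditional quantile function — every estimator can be checked against a
recoverable truth, and the full analysis workflow (`analysis/01_simulate.R`
… `analysis/04_report.R`) runs end to end on it.

## Worked example

```r
library(countqr)
gen <- generate_credits_data(n = 649, seed = 42)   # synthetic cohort
dataset <- gen$dataset

grid <- build_candidate_models()[c(1, 3)]             # linear baseline vs selected
fitted <- fit_model_grid(grid, dataset)
loss_table(fitted)
#>     model parameters     loss
#> 1 Model 0         22 339.4208
#> 2 Model 2         26 337.8666

fit <- fitted[[2]]$fitted
w <- wald_test_global(fit, 3)                      # cohort-2019 row
#> cohort effect: Wald = 45.35, df = 7, p = 0.000

beta_curve_band(fit, 3, c(0.1, 0.5, 0.9))          # cohort coefficient curve
#>     p estimate    se  lower  upper
#> 1 0.1   -0.398 0.115 -0.625 -0.172
#> 2 0.5   -0.171 0.219 -0.599  0.258
#> 3 0.9   -0.897 0.218 -1.325 -0.469

x_ref <- c(1, 0, 1, 0, 0, 0, 0, 0, 0, 0, 0)        # average student, cohort 2019
predict_quantile_count(fit, x_ref, 0.5)
#> [1] 10

gof_test(fit, dataset, "KS", n_mc = 100, seed = 1)
#> GOF: KS = 0.0156, Monte Carlo p = 0.54
```

Reading the output: the 26-parameter model improves the integrated loss over
the linear baseline; the global Wald test rejects "no cohort effect at any
quantile" on this synthetic cohort (whose generator includes a true negative
cohort effect concentrated in the tails — visible in the band: significant
at p = 0.1 and 0.9, not at the median); the median number of credit units
for the reference 2019 student is 10 (times 3 gives 30 credits); and the
PIT-based goodness-of-fit test does not reject the fitted specification.

The numbered scripts under `analysis/` run the same steps as a narrative
workflow — simulate the cohort, fit the jittering estimator over the
percentile grid, fit and compare the five-model grid, and write the
report tables (coefficient/SE tables for both methods, average-SE ratios,
the cohort-coefficient overlay) under `results/`.

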