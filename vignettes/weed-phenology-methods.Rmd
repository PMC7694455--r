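---
title: "Models and methods behind phenokit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phenokit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

phenokit analyses the demography of annual grass weeds (the motivating case
is *Vulpia myuros* alongside *Apera spica-venti*, *Alopecurus myosuroides*
and *Lolium multiflorum*) growing in monoculture and in winter wheat. This
vignette describes the statistical models, the choices that were genuinely
open when the package was designed, and what the synthetic-data generator
does and does not emulate.

## Thermal time

Every model uses cumulative thermal time (growing degree days) rather than
calendar time as its x-axis. A day's contribution is
`max(0, (tmax + tmin)/2 - Tb)` with base temperature `Tb = 1` degree C, the
value used for winter cereals and their accompanying grasses; days whose
mean temperature is at or below the base contribute nothing. Accumulation
starts on the sowing day itself: sowing-day growth belongs to "time from
sowing", and the value for the day before sowing is defined as zero. Soil
temperature drives emergence analyses (germinating seeds sit at shallow
depth), air temperature drives growth and phenology; the series carries its
source tag so downstream code can check it, but the accumulation itself is
source-agnostic — nothing in the package assumes a measurement depth.

Missing single days may be filled by linear interpolation of the
neighbouring days' `tmin`/`tmax`, but only when `allow_gap_fill = TRUE`;
the default is a hard error, because silent gap-filling of weather records
is a classic source of irreproducible degree-day sums.

## Emergence: grouped time-to-event fitting

Cumulative emergence follows the two-parameter log-logistic curve

$$E(t) = \frac{1}{1 + \exp[b(\log t - \log GERM50)]},$$

with `b < 0` for an increasing curve (the sign convention in which field
studies print their tables; `fit_emergence()` warns and keeps the sign if
data imply the opposite). Seedling counts are inspections of a cohort, so
the data are grouped event times: a seed observed emerged between
inspections $t_{j-1}$ and $t_j$ contributes
$\log[E(t_j) - E(t_{j-1})]$ to the likelihood. By default the final
observed count is treated as the emerging population (conditional-on-
emergence fit), which reproduces curves normalised to 0–100 % without
knowing viable seed numbers; when the number of seeds sown is known,
`use_n_sown = TRUE` adds the right-censored term
$(N - n_k)\log[1 - E(t_k)]$ for seeds never seen to emerge.

Optimisation is on $(b, \log GERM50)$ — the log scale keeps GERM50
positive and makes the sampling distribution closer to normal — with
starting values from a logit-linear regression of empirical cumulative
proportions on $\log t$, BFGS with a Nelder–Mead fallback, and a relative
objective tolerance of $10^{-10}$. The covariance is the inverse observed
information at the optimum.

Quantiles invert the curve analytically,
$t_p = GERM50\,((1-p)/p)^{1/b}$, so GERM10 · GERM90 = GERM50² exactly
(log-symmetry). Confidence intervals use the delta method on $\log t_p$;
refitting a reparameterised model would be the main alternative, and the
delta method was adopted because it needs no second optimisation and its
intervals are labelled as such in reports. Parameter comparisons between
fits are two-sided Wald tests with a normal reference, the post-hoc style
standard for these designs.

Whether counts should be pooled per plot or kept per quadrat before
fitting is left to the caller: `fit_emergence()` pools whatever units it
is given, and grouping is a subsetting decision, not a hard-coded rule.

## Growth: Weibull and log-logistic biomass curves

Per-plant dry matter over thermal time is fitted with either the
three-parameter Weibull
$Y = d\exp\{-\exp[-|c|(\log t - \log e)]\}$
or the log-logistic
$Y = d/(1 + \exp[c(\log t - \log TIME50)])$,
chosen per season as configuration (different climatic conditions make one
or the other family fit better; the family is never selected by an
information criterion inside the package). Published tables print the
Weibull rate as a positive magnitude although the curve increases; the
implementation therefore applies $-|c|$ inside the exponent and reports
$|c|$, so either sign can be supplied. TIME50 is the timing parameter
itself for the log-logistic and $e(\log 2)^{-1/|c|}$ for the Weibull;
because the printed Weibull timing column is ambiguous between the scale
parameter and the computed half-time, reports emit both.

Fitting is homoscedastic least squares on the original response scale (no
variance model is assumed; `log_response = TRUE` exists for strongly
fanning data but is off by default), by Levenberg–Marquardt over a small
grid of starting rates — steep, step-like profiles make a single start
fragile, and a rate that runs away to a near-step optimum is accepted with
`NA` standard errors rather than failing, since its fitted values and
residual sum of squares remain well defined. Model adequacy is checked by
the classical lack-of-fit F-test against the saturated one-mean-per-
sampling-time model, which requires replicate samples at shared times.

Crop suppression is summarised by the ratio of upper limits
$d_{+crop}/d_{-crop}$, with a first-order delta-method standard error from
the two independent fits and a Wald test against a ratio of one (the null
the printed p-values imply without stating). Dividing per-plant biomass by
quadrat plant counts is a documented reader step upstream of the model.

## Phenology: Monte-Carlo imputation-permutation

BBCH stage attainment is scored at fixed visits, so each plant's
attainment time is known only to an interval. Rather than pick a point in
each interval — conclusions would depend heavily on the pick when
intervals span whole stages — the package integrates over all exact times:
each Monte-Carlo iteration imputes one exact time per plant, uniformly
within its interval, computes the observed statistic
$|\bar{t}_A - \bar{t}_B|$ on the imputation, then permutes the group
labels once and recomputes it. The p-value is the add-one estimator
$(1 + \#\{S^* \ge S\})/(1 + n_{iter})$ with 1000 iterations by default.
How imputation and permutation interleave is not dictated by the method's
description alone; one fresh imputation per iteration with the statistic
re-drawn on it was adopted because it is unbiased under the null, keeps
every iteration exchangeable, and reduces exactly to a standard
permutation test when the intervals are degenerate (zero-width intervals
consume no random numbers, so the RNG stream matches the uncensored
procedure — a property the test-suite oracles rely on). The statistic is
two-sided; pairwise species comparisons are emitted unadjusted in the
post-hoc style, with Holm adjustment behind a flag. Plants that never
reached a stage carry no interval and are excluded by the caller.

Uncertainty of mean attainment times uses a nonparametric percentile
bootstrap (10 000 resamples, 95 % coverage by default): plants are
resampled with replacement and exact times are re-imputed within each
resample, so interval width and between-plant variation both enter the
interval. The point estimate is the mean of the resampled means.

## Fecundity: panicle-length calibration

Seeds per panicle are regressed on panicle (or head) length by ordinary
least squares — a straight line with intercept, since "correlation" alone
does not fix the functional form and the intercept costs one degree of
freedom on ~30–45 records. A plant's seed production is the sum of
per-panicle predictions, clamped at zero per panicle (a short panicle must
not subtract seeds) and rounded at the plant level. Calibration records
from plants with and without crop are pooled by default, matching practice
when the crop effect on the relation is nonsignificant.

Suppression of fecundity is the ratio of group means (+crop / −crop).
Ratio-of-means was chosen over mean-of-ratios because the design is
unpaired; a label-permutation test (1000 iterations) supplies the p-value
and a within-group percentile bootstrap (10 000 resamples) the CI.

## Competition: hyperbolic target-neighbourhood model

The response of a target plant to neighbouring wheat density $x$ is
$Y = a/(1 + x/DENS50)$: $a$ is the response growing alone and DENS50 the
density that halves it — larger DENS50, more competitive weed. Least
squares with DENS50 optimised on the log scale (positivity), starting from
the mean response at zero density and the design density whose mean
response is nearest $a/2$. A flat response profile leaves DENS50
unidentified and is flagged `converged = FALSE` rather than reported. The
six-density design (0, 48, 96, 192, 288, 576 plants m⁻²) is carried by the
generator as given; the pot-to-area mapping is validated, not re-derived.
DENS50 comparisons between species, crop stages or harvests are Wald
tests, as for the emergence parameters.

## The synthetic-data generator

No field data accompany the motivating study, so `scenario_config()` plus
the `gen_*()` generators produce all six input streams with the
distributional structure the models assume: log-logistic emergence times
tallied at an inspection schedule; curve-mean biomass with truncated
Gaussian noise; normally distributed latent stage times bracketed by a
scoring grid; log-normal panicle lengths with Poisson seed counts; and
hyperbolic pot responses. The generating parameters default to the
published season-specific estimates (e.g. *V. myuros* emergence
b = −5.0, GERM50 = 197 degree C day in 2017/18), so tests run at
field-realistic magnitudes. Design sizes mirror the trials: 10 or 6
emergence counts per season, ~19 seedlings per 0.25 m² quadrat (75
plants m⁻² target density), 6 biomass samplings on 3 plots, 15 marked
plants per species, the six-density pot design with 4 replicates. Noise
defaults to 10 % of the relevant scale where no variance estimate is
derivable from printed standard errors.

What the generator does **not** emulate: spatial correlation within plots,
seed dormancy and seedbank carry-over, weather realism beyond a sinusoid
with daily noise, death of marked plants, and any dependence between
streams (the same plants' emergence, growth and fecundity are drawn
independently). Passing round-trip tests therefore demonstrates that the
estimators recover the parameters of their own generating models at
realistic sizes and noise — internal statistical correctness — not that
the models describe real field data; the lack-of-fit machinery exists
precisely because the latter must be checked per dataset.

## Numerical choices and problem sizes

Tolerances: emergence likelihood optimisation `reltol 1e-10`; nonlinear
least squares `ftol 1e-12` with a 300-iteration cap; quantile/CDF and
TIME50 inversions are asserted to 1e-9 relative tolerance in the tests.
Ties in the permutation test count as exceedances (`>=`), which keeps
p = 1 for fully degenerate data. Reported stochastic results always carry
their iteration counts; the pipeline requires an explicit seed.

Simulation-based test sizes were chosen to give stable verdicts at
moderate cost: 200 replicates for parameter-recovery and type-I checks
(binomial slack bands around the 5 % nominal level), 300 for null-rejection
and bootstrap-coverage properties with 300–1000 resamples inside each
replicate. The full suite runs in well under a minute on one core.

## Known limitations

- The emergence fitter treats units as exchangeable within a fit; there is
  no mixed-effects structure over plots or blocks.
- Delta-method intervals for quantiles and ratios are first-order; at very
  small slopes or near-zero denominators they will be anticonservative.
- The conditional-on-emergence default cannot estimate the fraction of
  seeds that never emerge; supply `n_sown` for that.
- Hydrothermal-time models, dormancy, AFT/Turnbull interval-censored
  estimators and stage-duration models are out of scope by design.
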