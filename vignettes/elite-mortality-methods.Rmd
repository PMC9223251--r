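---
title: "Measuring the long-run mortality advantage of elite cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the long-run mortality advantage of elite cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elitemort)
```

`elitemort` compares the mortality of an elite cohort — the motivating case
is national politicians followed over two centuries — with the general
populations they belong to. Two complementary views are produced: relative
inequality as standardised mortality ratios (SMRs) over calendar time, and
absolute inequality as gaps in remaining life expectancy at age 45. This
vignette is the package's own account of the models, the conventions behind
them, and the choices made where the design was genuinely open.

## The comparison problem

An elite cohort has no natural control group. The comparator used here is
the period life table of the cohort's own country: for every year of every
person's follow-up, the life table says how likely a person of that age,
sex and calendar year was to die. Summing those cell-level expectations
yields the deaths the cohort *would* have experienced under population
mortality; the ratio of observed to expected deaths is the SMR (indirect
standardization).

Two well-known traps shape the whole design:

* **Immortal time bias.** A politician cannot die before being elected, so
  person-time before office entry is artificially death-free. All
  follow-up therefore starts at the office date, never at birth.
* **Pro-rata first-year exposure.** Someone elected half-way through a
  calendar year is only at risk for half of it; their expected deaths for
  that year must be exactly halved.

## Person-year expansion and expected deaths

Follow-up is cut at every January 1 and every birthday, so each slice lies
in a single Lexis cell (one calendar year × one integer age), and ends at
the earliest of death, the last year with life-table data, or an optional
follow-up horizon. Exposure is measured in days / 365.25, and the death day
itself is not counted as exposure.

Each slice contributes `exposure × mu` expected deaths, with
`mu = -log(1 - qx)` the constant hazard implied by the matched death
probability. This convention was chosen over `exposure × qx` because it is
exactly linear in exposure — the half-year contract above holds to machine
precision, and expected deaths are additive over any further subdivision of
slices. The cohort simulator draws death times by inversion of the same
piecewise-constant cell hazards, so the generator and the estimator share
one discretization; the test suite verifies the slice engine against an
independent day-by-day accumulation at 1e-8 relative error.

Age at risk is the exact attained age (slices are cut at birthdays), not
age on January 1; published cohort analyses are usually silent on this
point, and either convention is defensible — cutting at birthdays keeps
the matching exact. Deaths after the last life-table year are censored at
December 31 of that year: they contribute neither observed nor expected
deaths.

## Exclusions and anomaly flags

A record is retained when its birth date is present, its death date is
present *if the person is known to be dead*, and its office year falls
inside the life-table span. "Death date missing" is genuinely ambiguous
for historical registers: someone with no recorded death may be alive, may
be lost to tracking, or may be dead with an unrecorded date. The schema
therefore carries an explicit vital-status column; only `dead`-without-date
records are excluded, while `alive`/`unknown` records are censored at the
last life-table year. Anomalies that in real scraped data signal clerical
errors — death within 183 days of taking office, entry before age 21,
apparently alive beyond 102 — are flagged for review but never silently
dropped. The 183-day and age-102 thresholds are package defaults, exposed
as arguments.

## Interpolating gapped life tables

Early historical tables exist only every 5 or 10 calendar years. Gaps are
filled on the log cumulative-hazard scale `z = log(-log(1-qx))`, where
back-transformed values always land in (0, 1]. Because every observed year
carries a complete age column 0..ω, the two-dimensional grid interpolation
reduces to a natural cubic spline across calendar years at each age; the
result reproduces the observed years *exactly*. An earlier design used a
penalized tensor-product smooth chosen by cross-validation as the
interpolant itself; that was abandoned because any amount of smoothing
trades away exact reproduction of the published tables, which downstream
expected-death matching should treat as data, not as noisy estimates. The
cross-validated tensor smooth over (age, year) is retained as a
*diagnostic*: the residual report (per-sex residual SD, skewness, outlier
count) automates the usual visual check of interpolation quality.
Extrapolation beyond the observed year range is refused.

On surfaces generated from a smooth log-hazard with constant proportional
improvement, annual reconstruction is accurate to well under 2% relative
error in `qx` (the acceptance suite checks this bound; the year-linear
log-hazard of the generator is recovered to machine precision).

## Remaining life expectancy conventions

Life-table `e(x)` uses the uniform-deaths convention: half a year lived in
the year of death, including the open terminal interval (ω = 110 by
default, where `qx` is taken as 1). Pooled population values average
single-year `e(45)` over a window's calendar years per sex, then mix the
sexes with the cohort's male fraction — because elite cohorts were
overwhelmingly male for most of history, comparing them against a 50/50
population would overstate their advantage.

## The SMR trend model

Yearly SMRs are noisy (small cohorts early on); the trend is smoothed with
a Bayesian Poisson regression using expected deaths as an offset:

  observed_t ~ Poisson(expected_t × exp(f(year_t)))

with `f` either linear or a B-spline in calendar year. Candidate bases
(linear, B-spline with 2 or 3 degrees of freedom) are compared by DIC,
`DIC = D̄ + pD` with `pD = D̄ − D(posterior mean)`; ties within 0.5 go to
the simpler basis. The df-2 spline uses a quadratic basis because a cubic
B-spline needs at least three degrees of freedom; the df-3 spline is cubic
with interior knots at quantiles of the observed years.

Posteriors come from a blocked random-walk Metropolis sampler with weakly
informative Normal(0, 10²) priors, the proposal scaled from the Poisson
GLM curvature, 4 chains × 5,000 retained draws by default, with split-R̂
convergence checks (fits with R̂ > 1.05 are flagged, never silently
accepted). A bespoke sampler was preferred over a general MCMC engine
because the models have only 2–4 coefficients, the GLM-curvature proposal
mixes well, and the result is seed-deterministic with no model
compilation; on simulated linear declines the posterior slope is
well-calibrated and the 95% credible band covers a known truth at close to
nominal rates (the suite requires 90–98% over years × replicates). Years
with zero expected deaths (no cohort at risk) are dropped, not imputed.

Direct standardization with WHO World Standard Population weights
(packaged, user-overridable) is the sensitivity check for shifting age
structure: band-level cohort death rates and identically weighted
population rates are compared over bands where the cohort has person-time;
bands without exposure are reported rather than silently zeroed into the
comparison.

## Gompertz windows and life-expectancy gaps

Absolute inequality is measured in consecutive 10-year calendar windows.
Within each window the cohort's mortality is modelled with a Gompertz
proportional-hazards law on the age scale,

  h(a) = b · exp(g (a − 45)) · exp(β_sex · female),

fit by maximizing the left-truncated (entry age into the window),
right-censored log-likelihood. Parameterizing `b` at age 45 — near the
centre of the data — is a pure reparameterization that conditions the
optimizer; the covariance comes from the observed information. The default
is a single fit per window with a proportional sex effect, with
`sex_covariate = FALSE` available for separate handling; life expectancy
is mixed over sexes with the window's exposure-weighted male fraction,
mirroring the pooled population comparator.

Remaining life expectancy integrates the fitted survival function by
adaptive quadrature, truncated where survival drops below 1e-12. The
`g → 0` limit (exponential lifetime, `e = 1/b`) is handled by the same
code path via series expansion. For `g < 0` the integral is genuinely
improper when the cumulative hazard plateaus below the truncation point —
a positive fraction of the population would never die — and the function
returns `Inf` with a warning rather than pretending otherwise.

The gap is the cohort's `e(45)` minus the pooled population `e(45)` over
the same window (period life tables averaged over the window years — the
population side is *not* a fitted Gompertz, so the comparison does not
inherit the model's parametric assumptions on both sides). CIs come from
bootstrapping individuals — not person-year slices, since a person's
slices are strongly dependent — 1,000 times by default, with the
percentile 2.5/97.5 interval; windows where more than 10% of resamples
fail are flagged unreliable. Windows with fewer than 30 events are
reported unestimable rather than extrapolated.

**A caution on young windows.** In the first decades of a cohort nobody
has aged far beyond the entry ages yet, so a window can have enough events
and still contain no information about old-age hazards; the Gompertz slope
is then extrapolated and the life expectancy badly determined (the wide
bootstrap CI signals this). The recovery checks in the test suite
therefore evaluate windows that begin 30 years after entries start, where
ages 45–100 are populated. Real analyses should read early windows with
the same caution.

## The synthetic-data generator

Since real politician registers cannot be redistributed, every stage is
exercised against generated data with known truth. Population mortality is
Gompertz–Makeham per sex — background hazard `a`, level `b0` at age 45,
age slope `g` — declining proportionally at 1% per calendar year; the
defaults (males `a = 5e-4, b0 = 0.012, g = 0.085`; females
`a = 4e-4, b0 = 0.008, g = 0.090`) give remaining life expectancies at 45
of roughly 20 years in 1850 rising to the high 30s by 2015, in line with
long-run historical experience. Table `qx` values integrate the hazard
exactly over each one-year age interval, so the discrete life table and
the continuous truth agree in `e(45)` to within 0.001 years. The cohort's
hazard is `hr(year)` times the population hazard with constant, linear or
logistic-decline shapes; the default logistic decline from ~1 to 0.55
centred on 1950 mirrors the qualitative finding that motivated the
package. Entry dates are uniform over the span, entry ages
truncated-Normal(45, 7²) on [25, 75], and the female share is zero before
1920 rising linearly to 20% — so early windows are male-only, as in
history. Death times are drawn by exact inversion of the per-cell
cumulative hazard (validated against a day-step Bernoulli oracle by
Kolmogorov–Smirnov distance), and all generators are seed-deterministic.

What the generator does *not* emulate: infant-mortality humps and war/
pandemic mortality shocks (the hazard surface is smooth in both age and
year), country-specific calibration, cause-of-death structure,
heterogeneous frailty, and real loss to follow-up. Passing tests therefore
demonstrate that the estimators recover known truths under clean
conditions with realistic magnitudes — not that any historical dataset is
free of the data problems the cohort module's flags are designed to
surface.

## Problem sizes and numerical choices

The validation suite uses cohorts of 20,000 for SMR and gap recovery
(binding the pooled SMR within ±0.03 of hazard ratios 1 and 0.6, and
window gaps within 0.5 years of the analytically integrated truth), 5,000
for Gompertz parameter recovery, 100 bootstrap-coverage replicates at
n = 2,000 with B = 200, and 20 replicates for trend model selection and
credible-band coverage — sizes chosen so each property is tested at
meaningful power while the whole suite stays desk-scale. Quadrature uses
`rel.tol = 1e-10` with survival truncated at 1e-12; `qx` is clamped below
1 by 1e-10 before hazard conversion so the open terminal age stays finite;
exposure uses days/365.25 with Feb 29 birthdays mapped to Mar 1 in
non-leap years.

## Reproducing the workflow

The numbered scripts under `analysis/` run the whole study on the default
scenario: `01_simulate.R` writes the life tables and cohort,
`02_prepare_lifetables.R` annualizes the tables, `03_smr_trend.R` computes
SMRs, the DIC-selected trend and the direct-standardization check,
`04_le_gaps.R` the windowed life-expectancy gaps with bootstrap CIs, and
`05_followup_sensitivity.R` the follow-up-horizon robustness ladder.
`scripts/acceptance.R` recomputes the headline recovery quantities from
scratch for any seed.
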