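# elitemort

Comparative mortality of elite cohorts against their general populations,
over the long run of history.

Elite groups — the motivating case is national politicians, for whom birth,
death and office dates survive across two centuries — offer a rare window
on how health inequality evolved before routine record linkage. `elitemort`
implements the full comparison pipeline against period life tables:

* **Relative inequality.** Each person is followed from the date they
  attained office (avoiding immortal time bias — nobody can die before
  being elected), their follow-up expanded into person-year Lexis slices
  matched by country, calendar year, age and sex to the life table. The
  standardised mortality ratio for year *t* is

  SMR_t = observed deaths_t / Σ exposure × (−log(1 − qx)),

  with first-year exposure pro-rated from the office date. Trends are
  smoothed with Bayesian Poisson regression using expected deaths as an
  offset, `observed_t ~ Poisson(expected_t · exp(f(t)))`, the basis for
  `f` (linear, B-spline df 2 or 3) chosen by DIC. Direct standardization
  with WHO World Standard Population weights checks the cohort's shifting
  age structure, and a 10–60-year follow-up-horizon ladder probes unknown
  loss to follow-up.

* **Absolute inequality.** In consecutive 10-year windows, a
  left-truncated Gompertz proportional-hazards model on the age scale,
  `h(a) = b·e^{g(a−45)}·e^{β·female}`, gives the cohort's remaining life
  expectancy at 45, compared with the gender-pooled population value from
  the same window's life tables; 95% CIs from 1,000 bootstrap resamples
  of individuals.

* **Infrastructure.** An HMD-style 1×1 life-table reader/writer, annual
  interpolation of 5- or 10-yearly tables on the log cumulative-hazard
  scale (observed years reproduced exactly, with a residual diagnostic
  report), exclusion rules with a reconciling report, anomaly flags for
  suspect records, and a synthetic-data generator whose hazard ratios,
  SMR curves and life-expectancy gaps are known analytically — so every
  stage is tested against ground truth without any external download.

## Worked example

The numbered scripts under `analysis/` run the whole study on a bundled
synthetic scenario: an 1850–2015 cohort of 10,000 politicians whose
hazard ratio against a Gompertz–Makeham population declines logistically
from about 1 to 0.55 across the twentieth century, with life tables
published only every 5 years.

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_prepare_lifetables.R
Rscript analysis/03_smr_trend.R
```

Step 3 prints:

```
pooled SMR over the whole span: 0.762
DIC table:
       basis    df      dic      p_d converged
1:    linear     1 1118.850 2.036105      TRUE
2: bspline-2     2 1113.192 3.023856      TRUE
3: bspline-3     3 1095.333 3.903115      TRUE
selected basis: bspline (df=3)
fitted SMR: ~0.95 in the 1850-60s vs ~0.56 after 2005 — the elite survival
advantage emerges over the twentieth century
```

The pooled SMR of 0.762 says the cohort experienced about three-quarters
of the deaths expected under population mortality; the DIC-selected cubic
spline resolves *when* the advantage appeared — fitted SMRs near 1 in the
nineteenth century falling to ~0.56 in recent years, tracking the known
generating hazard-ratio curve. Step 4 converts this into years of life:

```
16 of 16 windows estimable
largest gap: 6.3 years (95% CI 5.3-7.4) in 2000-2009; politician e(45) 42.5
vs population 36.1
```

and step 5 re-estimates pooled SMRs under follow-up horizons of 10–60
years, the robustness check against passively tracked deaths.

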