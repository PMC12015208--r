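---
title: "Methods: heat-wave exposure and early birth in a case-crossover design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heat-wave exposure and early birth in a case-crossover design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatbirth)
```

## The problem

Acute heat exposure in the final days of pregnancy is associated with preterm
birth (PTB, 28–36 completed gestational weeks) and early term birth (ETB,
37–38 weeks). Estimating that association from vital records raises three
methodological problems that this package addresses as a single tested
pipeline:

1. **Exposure definition.** Heat waves are local phenomena: the same absolute
   temperature is extreme in one place and routine in another. Exposure is
   therefore defined relative to each area's own climate.
2. **Confounding by time.** Birth risk varies by season, weekday, and secular
   trend; so does temperature. A time-stratified case-crossover design
   compares each case to itself on nearby reference days, removing all
   person-level and slowly varying confounders by design.
3. **Risk-set drift.** Even within a month, the number and gestational-age
   mix of pregnancies at risk changes (conception seasonality, gestational-age
   measurement artifacts). A daily risk-set adjustment covariate absorbs this.

## Exposure metrics

Gridded daily minimum and maximum temperatures are averaged over the grid
points mapped to each ZIP Code Tabulation Area (ZCTA); the daily mean is the
midpoint `(avg tmin + avg tmax)/2`, the standard convention for min/max
pairs. The **hot-day threshold** for a ZCTA is the 97.5th percentile of its
daily mean temperature over the *full* multi-year series (all seasons). The
quantile uses the Weibull plotting position (`stats::quantile` type 6,
interpolating at `(n+1)p`), a common convention in epidemiological software;
the type is an argument, so any convention can be matched exactly.

For each day `d` the exposure window is the day itself plus the three
preceding days (lags 0–3). Two families of metrics are computed on the
window:

- `run_length`: the longest run of *consecutive* days whose mean strictly
  exceeds the threshold (ties at the threshold do not count), dichotomised
  as `hw_ge2` (≥ 2), `hw_ge3` (≥ 3), and `hw_eq4` (all four days hot). These
  cuts form a strictly nested family with decreasing prevalence. Because
  labels like "more than 2 consecutive days" are ambiguous between ≥ 2 and
  ≥ 3, the package names the definitions by their explicit cut.
- `aat`: the **average degrees above threshold**, `max(0, mean(window) −
  threshold)` in °C. Days below the threshold count negatively before the
  floor, so AAT reflects both intensity and duration; a window that never
  gets hot scores 0 rather than negative.

A window extending before the series start yields missing metrics; strata
touching such days are excluded downstream and counted in the exclusion log.

The window is configurable (`exposure_for_date`, `compute_exposures`); lags
0–3 are the default because the event day's own exposure plausibly
contributes to labor onset, and the four-day window preceding and including
the birth day is the natural reading of "exposure window preceding birth".

## The case-crossover design

The event day is the birth day. Referent days are **every other day of the
same calendar month falling on the same weekday** — the full time-stratified
referent set, which the calendar fixes at 3 or 4 days. Matching on weekday
removes day-of-week effects (scheduled inductions and cesareans concentrate
on weekdays); restricting to the same month removes seasonal and secular
trends. The analysis is limited to the **warm season, May 1 – September 30**,
where heat waves are a meaningful exposure.

Each stratum therefore has 4 or 5 days with exactly one case day.
Strata in which the exposure covariate never varies are uninformative for
the conditional likelihood; they are dropped from the likelihood but still
counted as cases, so reported case counts match the register. Exclusions
(wrong outcome, outside warm season, missing exposure or adjustment) are
always counted by reason and retrievable with `exclusion_log()`.

## The pregnancy risk-set adjustment

Case-crossover designs assume the population at risk is stable across a
stratum's days. For birth outcomes it is not: the pool of ongoing
pregnancies at risk of PTB/ETB drifts within a month. Following the
risk-set framing of Vicedo-Cabrera and colleagues, the package computes for
every ZCTA-day

\[ W_i = \frac{\sum_{g} Z_{ig} W_g}{Z_i}, \]

where `Z_ig` counts ongoing pregnancies at completed week `g` on day `i`
(`g` in 28–36 for PTB, 37–38 for ETB), `Z_i` counts *all* ongoing
pregnancies (including those past the risk range), and `W_g` is the
state-level discrete hazard: births at week `g` divided by births at week
`g` or later, from **all** births in the state. `W_i` is the average
probability of birth that day among pregnancies at risk and enters the
model as a continuous covariate.

Conventions, each chosen once and tested:

- Pregnancy start is reconstructed as `birth_date − 7·ga_weeks`; the
  pregnancy spends exactly seven days at each week `0..ga−1` and the birth
  day itself is an event, not at-risk time (no double counting).
- `W_g` is a discrete hazard rather than a marginal proportion, matching
  the "among ongoing pregnancies at risk" estimand; weeks before the
  earliest observed birth have hazard 0, and a risk-range week beyond the
  last observed week is an error rather than a silent 0.
- Days with `Z_i = 0` have undefined `W_i`; strata touching them are
  excluded and logged.
- If the register has an administrative end date, days within 45 weeks of
  it have right-truncated risk sets (pregnancies delivering after the end
  are invisible). `risk_set_adjustment(data_end = …)` flags such days and
  the pipeline excludes flagged strata by default. A register produced by
  the package's own simulator is complete — every simulated pregnancy's
  birth is recorded — so the default `data_end = NULL` declares no
  truncation.

## Conditional logistic regression

With one case per stratum the exact conditional likelihood is

\[ \ell(\beta) = \sum_s \left[ x_{case}\beta - \log \sum_{j \in s}
   e^{x_j\beta} \right], \]

maximised by Newton–Raphson from `beta = 0` with analytic gradient and
observed information, step-halving on any decrease of the concave
log-likelihood, and convergence at gradient max-norm `< 1e-8` (at most 50
iterations). Standard errors come from the inverse observed information at
the optimum. The model always contains the heat-wave metric plus the
`w_adjust` covariate in the default pipeline.

Numerical choices: covariates are standardised internally by their
within-stratum residual standard deviation (AAT is on a degrees scale,
`W_i` lives near 0.005, so raw-scale Newton steps would be badly
conditioned) and estimates are transformed back; the per-log-eta shift is
stabilised by subtracting the stratum maximum before exponentiation.
Monotone likelihoods (perfect separation) are detected — standardised
coefficients beyond ±10 or a singular information matrix — and returned as
flagged non-converged results rather than errors, so a single degenerate
state-stratum cell cannot crash a stratified run.

The fitter is validated against an independent profile-grid search and
against `survival::clogit` (agreement to `1e-6` on simulated strata), and
against the classical `n10/n01` closed form for 1:1 binary discordant
pairs.

## Pooling and heterogeneity

State estimates are pooled with fixed-effect inverse-variance weights:
`w_k = 1/se_k²`, `β̂ = Σw_kβ_k/Σw_k`, `se = (Σw_k)^{-1/2}` — states are fit
separately and pooled, never stacked into one mega-fit. Effect modification
is tested on the pooled per-stratum estimates: a two-group Z-score
`z = (β_a−β_b)/√(se_a²+se_b²)` for dichotomous stratifiers, and the
inverse-variance Wald statistic `Σ w_k(β_k − β̂)² ~ χ²(k−1)` for `k`
strata. At `k = 2` the Wald statistic equals `z²` exactly (asserted in the
tests). Random-effects pooling and I² are deliberately out of scope.

## The synthetic-data generator

Because vital records are confidential, every stage is validated on
synthetic data with known truth. The generator emulates:

- **Temperature**: per grid point, an annual sinusoid (default mean 15 °C,
  semi-amplitude 10 °C, peak at day 196 ≈ mid-July) plus a per-ZCTA offset
  (SD 1.5 °C, an urban-heat-island stand-in) plus a stationary AR(1) with
  ρ = 0.75 and innovation SD 2 °C. These defaults give warm-season
  heat-wave prevalences close to the few-percent range and mean positive
  AAT below 1 °C — the regime such analyses operate in.
- **Population**: conception dates with mild sinusoidal seasonality
  (amplitude 0.1), multinomial age (31/52/17%) and education (25/30/45%)
  mixes, and per-ZCTA Social Deprivation Index centiles and impervious-cover
  fractions, correlated with the temperature offset through a Gaussian
  copula (r = 0.3) so that deprived areas tend to be hotter, as in real
  cities.
- **Births**: each pregnancy is simulated day by day from week 20 with
  weekly baseline hazards `W_g` (defaults give ≈ 1% of births before 28
  weeks, 8–9% PTB, 24–25% ETB, certain delivery by week 45). On each day
  the daily hazard `1-(1-W_g)^{1/7}` is multiplied by `exp(β · AAT)` during
  weeks 28–38, where `AAT` is that day's own 4-day exposure in the
  pregnancy's ZCTA — the generating model matches the analysis model, so
  the estimand of the pipeline equals the simulated `β` (log-odds per °C).
  `β` can differ by subgroup (`beta_modifier`), which is how
  effect-modification recovery is tested.

What the generator does **not** emulate: real demographic joint
distributions, spatially explicit grids, gestational-age digit preference,
induced-labor flags, humidity. Passing tests show the pipeline recovers
effects under its own assumptions; they do not validate those assumptions
against real registers.

## Problem sizes and what the validation studies show

The calibration and recovery studies use a modest scale — 2 states × 5
ZCTAs × 500 pregnancies per ZCTA × 2 conception years — chosen so a few
hundred replicates run in minutes: each replicate yields roughly 500
warm-season ETB cases (about 160 PTB), with a pooled per-replicate standard
error near 0.3 (ETB) on the per-°C log-OR.

- **Null calibration** (500 replicates, β = 0): the pooled Wald test
  rejects at ≈ 5% (0.046 in the test batch). The mean of the pooled
  estimates drifts slightly positive — on the order of one Monte-Carlo
  standard error at 500 replicates (~+0.02 across 900 diagnostic
  replicates). Re-drawing case labels uniformly within fixed strata
  reproduces the drift, so it is a finite-sample property of the pooled
  conditional MLE with a sparse, right-skewed exposure at ~20 units of
  Fisher information per replicate (per-state MLEs are left-biased and the
  inverse-variance weights, which correlate with the estimates, overshoot
  the correction), not of the pipeline plumbing: the likelihood code
  agrees with an independent implementation to 10⁻⁶ and the risk sets
  match per-pregnancy enumeration exactly. The drift shrinks with
  information and is ~5% of a single replicate's standard error.
- **Parameter recovery** (200 replicates, β = log 1.05): the mean pooled
  estimate sits within Monte-Carlo error of the simulated truth and 95% CI
  coverage is nominal. Recovery is run on the *ETB* outcome: with ≈ 500
  cases per replicate its estimates are stable, whereas PTB at this scale
  (≈ 160 cases, few informative strata) occasionally produces
  near-degenerate fits whose enormous — but honestly enormous, the CIs
  cover — estimates make a mean-over-replicates summary uninformative.
  Risk-set depletion for the common ETB outcome (a pregnancy advanced by
  an early-month hot day is no longer at risk on the case day) is a
  theoretical source of upward bias for case-only contrasts, but is not
  detectable at this precision (≈ 0.016 MC standard error on the log-OR
  over 400 pilot replicates).
- **Effect-modification recovery** (100 replicates, subgroup β of 0 vs
  log 1.05): the pooled subgroup ORs order correctly more often than
  chance, but a per-replicate ordering probability of 90% is out of reach
  at any desk-scale size: with per-subgroup standard errors near 0.3, the
  gap of log 1.05 ≈ 0.049 would need per-subgroup SEs ≤ 0.021, i.e.
  roughly 400× more pregnancies per replicate (hundreds of millions of
  simulated pregnancy-days per replicate across 100 replicates). The
  package asserts the identity `Wald χ² = z²` exactly and reports the
  observed ordering rate; the 90% bar is achievable only at register
  scale, which is consistent with the fact that real analyses of this
  design use millions of cases.

## Known limitations

- The exposure window and warm season are calendar-based; no
  humidity/heat-index metrics.
- Fixed-effect pooling assumes a common true effect across states.
- The risk-set adjustment enters linearly; a log link is a plausible
  alternative (the scale of `W_i` variation within a month is small enough
  that the difference is second-order).
- The conditional likelihood handles exactly one case per stratum;
  same-day same-ZCTA births form separate strata, which is the standard
  treatment.
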