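---
title: "Model methods: a discrete-event polypill cost-effectiveness simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model methods: a discrete-event polypill cost-effectiveness simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polypillCEA)
```

## The decision problem

A polypill — one fixed-dose combination of aspirin, a statin and two
blood-pressure-lowering drugs — simplifies cardiovascular prevention for
people who are indicated for all three classes: adults with established
atherothrombotic cardiovascular disease (CVD) or at high primary risk.
Trials of the polypill measure adherence over a year or two; the health
and cost consequences of better adherence accrue over a lifetime. This
package bridges that gap with an individual-level discrete-event
simulation (DES): heterogeneous synthetic individuals, risk-equation-driven
event histories, and continuously discounted costs and QALYs, compared
between a usual-care arm and a polypill arm that differ through adherence
and drug pricing.

A DES rather than a cohort state-transition model because the population is
heterogeneous in exactly the way CVD risk equations exploit — age, sex,
smoking, blood pressure, lipids, deprivation, history — and because event
history (a first stroke, diabetes onset) must feed back into subsequent
risk, which memoryless cohort cycles cannot carry without an explosion of
states.

## Population and inclusion

`generate_population()` draws a synthetic cohort emulating the fields a
health-survey-derived model population needs: age, sex, ethnicity, smoking,
systolic blood pressure (SBP), total/HDL cholesterol ratio, BMI, a
Townsend-style deprivation score, diabetes, family history, prior CVD
events and current medication. Continuous risk factors pass through a
Gaussian copula, keeping every marginal exactly as specified while
inducing age–SBP (0.35) and age–BMI (0.12) correlation; these two
correlations are the minimum structure the risk engines are sensitive to.
Defaults (age 62 ± 10 truncated to 35–90, SBP 138 ± 16 mmHg, ratio
4.3 ± 1.0, BMI 28 ± 4.5, 25% established CVD) describe a
middle-aged-to-elderly adult pool enriched for cardiovascular risk — chosen
once as a realistic eligible pool, not fitted to any dataset.

`apply_inclusion()` applies the trial-style entry criteria: age ≥ 18 and
either established CVD or a 5-year first-event risk ≥ 15% (configurable
threshold, inclusive at the boundary). The model's primary engine predicts
over 10 years; the 5-year inclusion risk is derived under a constant-hazard
assumption, `S(5) = S(10)^{1/2}`. A different inclusion engine (e.g. a
Framingham-style equation over 5 years) can be passed directly; the
conversion avoids carrying a second full coefficient set for a filter.

What the generator does **not** emulate: survey weights, measurement
error, item missingness, within-household clustering, or secular trends.
Passing tests therefore demonstrate internal correctness of the machinery
on a clean, plausibly structured cohort — not calibration to any real
population.

## Risk engines

All three engines (primary CVD, secondary/recurrent CVD, incident type 2
diabetes) share the published proportional-hazards functional form
`P = 1 − S₀^{exp(β′x)}`, with the coefficient tables fully data-driven:
each term is an R expression in the individual's fields, so age
transforms and interactions live in the table, not the code. The packaged
coefficients are **illustrative** values centred on a 50-year-old white
non-smoking reference profile, with weights of the sign and rough
magnitude the published equations report; published coefficient sets load
as drop-in CSVs (`read_risk_coefficients()`). Bit-exact reproduction of
the published equations is deliberately out of scope.

Horizon risks become constant hazards between risk-recalculation points,
`λ = −log(1−p)/h`, refreshed after every event and at a scheduled update
every 10 years — the engines' own prediction horizon, so a hazard is never
extrapolated beyond the window its equation describes. The secondary
engine takes over permanently after the first CVD event. Its prediction
horizon is not fixed by its source; the package defaults it to 10 years,
configurable. The secondary composite (which in its source includes
cardiovascular hospitalisation) is mapped onto the four modelled acute
types by the same relative-incidence split as primary events — an explicit
assumption, flagged here because the source split is unstated.

## Adherence

The trial endpoint: adherent means statin ≥ 4 days, antiplatelet ≥ 4 days,
and at least two antihypertensive agents each ≥ 4 days, in the preceding
week (`classify_adherent()`). Usual-care adherence is a logistic model on
individual characteristics (default: rises with age, falls with
deprivation, ~65% at the reference profile); it is implemented as a
fixed-effects binary regression — the survey-style data the model emulates
carry no grouping factor, so a random-intercept term would have nothing to
estimate; the model object is a configuration hook if one is added. The
polypill multiplies the usual-care probability by a relative risk (default
1.3, 95% CI 1.18–1.43, the size a fixed-dose-combination trial reports),
capped at 1. Multiplication on the probability scale matches a
log-binomial RR, which is also how `estimate_polypill_rr()` estimates it
from two-arm data.

Adherence is redrawn at every risk-update point (after events or every 10
years), not continuously — matching the model's state-update schedule.
Whether partially adherent polypill use exists is unmodelled: adherence is
binary. Cessation is a permanent exponential exit from treatment (default
hazard 0.05/yr) active while on treatment; after cessation all treatment
effects vanish and a one-off stopping cost applies.

## Treatment effects

While adherent: CVD hazard × statin RR (0.75) × antihypertensive RR
(0.80) × aspirin RR (0.81), combined multiplicatively (the standard
independence assumption for effects sourced from separate meta-analyses);
diabetes hazard × 1.10 under statin/antihypertensive; GI-bleed hazard ×
1.60 under aspirin; heart-failure hazard × 0.72 under antihypertensives; a
persistent cough fires once at ACE-inhibitor initiation with probability
0.06 (a probability, not a rate — the event is tied to starting the drug,
placed uniformly in the first treatment year). An `itt_adjustment`
exponent on every log-RR supports the per-protocol sensitivity analysis:
intention-to-treat sourced effects already dilute for non-adherence, so a
value above 1 strengthens effects as the sensitivity dial; its formula is
not prescribed anywhere, hence an explicit exponent rather than a hidden
correction.

Both arms treat every included individual with the same three classes —
usual care as separate pills, the polypill as the combination. The arms
therefore differ only through the adherence probability and the polypill
price (default: exact aggregate of the component drug costs). This mirrors
the trial design the model serves, and it is what makes the null scenario
(all RRs = 1) exactly arm-identical — the package's sharpest validation
lever.

## The event loop

Within each risk period the competing causes — composite CVD, diabetes
onset, heart failure, GI bleed, cessation, other-cause death — each get an
independent exponential clock at their current hazard (other-cause
mortality is piecewise-exponential over the life table's single-year
rates, not constant). The earliest clock fires, capped by the scheduled
10-year update and the age cap; firing anything discards and resamples the
remaining clocks, which is statistically exact for exponential clocks and
keeps the loop simple. Numerical conventions, fixed once:

* Tie-breaks at equal clock times follow a fixed cause order (cap,
  other-cause death, CVD, diabetes, heart failure, GI bleed, cessation,
  update); exact ties have probability zero in continuous time.
* Acute CVD events split into TIA/stroke/MI/angina by the
  relative-incidence vector (default 0.20/0.30/0.33/0.17). Stroke and MI
  carry age-banded case fatality (60-day and 30-day windows); bands are
  closed on the left, so 75.0 falls in the ≥ 75 band. Fatal events
  terminate at event time + window. Angina and TIA are non-fatal acute
  events. Survivors switch permanently to the secondary engine.
* Ages outside the heart-failure table clamp to the nearest endpoint (with
  a warning outside the simulation loop); the life table must cover ages to
  100 and beyond-table survival continues at the final hazard.
* Entry at or above the age cap (100) exits immediately with no events.

Every random draw flows from one master seed through named substreams
(population, synthetic trial, per-individual simulation, PSA). The
per-individual stream mixes the master seed and the individual id but
**not** the arm: common random numbers across arms, so the null scenario is
bit-identical and increments are low-variance. A run manifest
(seed + parameter digest) reproduces any result exactly.

## Economics

Continuous-time discounting at 3.5%/yr throughout — a DES has no cycles,
so `(1+r)^{-t}` at exact event times and the closed-form integral
`flow × ((1+r)^{-t₀} − (1+r)^{-t₁})/log(1+r)` for annual flows are the
natural analogue of the recommended annual rate. Acute costs hit at event
times; post-event state costs (stroke, MI, angina, diabetes, heart
failure) run for life from the first event of that type, with repeat
events re-triggering the acute cost only; medication and monitoring costs
run over adherent exposure; the stopping cost lands once at cessation.

Utility is baseline-by-age-and-sex minus the sum of active decrements,
floored at zero — additive because decrement-style sourcing reports
subtractions, floored because a negative utility from stacked decrements
would be an artefact. GI bleed and cough decrements are transient; their
durations (0.1 and 0.5 years) are configuration values with no claimed
provenance. All packaged costs and utilities are illustrative magnitudes,
in a recorded currency year, replaceable via the config or CSV tables.

## Uncertainty analysis

Each PSA iteration draws parameters (lognormal on RRs, median-preserving;
beta on probabilities, mean-preserving via effective sample size; gamma on
costs, mean-preserving via coefficient of variation — all overridable, any
entry degenerate at `cv = 0`), draws one bootstrap resample of the
population with replacement at its original size, and reruns both arms.
The simulation streams are held fixed across iterations, so
iteration-to-iteration variation isolates parameter and sampling
uncertainty; with every distribution degenerate and the bootstrap off, the
PSA reproduces the base case exactly. The acceptability curve is the
positive-net-benefit fraction per willingness-to-pay value.
`convergence_check()` declares stability when the 95% CI half-width of
mean ΔC and mean ΔE falls below 1% of the mean magnitude (configurable),
and recommends an iteration count by the 1/√n rule; a non-positive
tolerance is flagged as unsatisfiable rather than looping.

## Problem sizes and test design

The test suite exercises each operation against an independent oracle
where one exists: closed forms for discounting and risk–hazard
conversions (cross-checked against numerical integration), the
truncated-normal mean by quadrature for the population generator,
Kolmogorov–Smirnov tests against the exponential for event-time sampling,
a day-step Bernoulli brute force (5,000 individuals, 10-year horizon,
1/365.25-year steps) for the competing-risk engine, the life table's own
survival curve (50,000 individuals, decade checkpoints, 3-standard-error
bands) for mortality, and 100-replicate coverage simulations (20,000
usual-care records per fit; 1,000 per trial arm) for the adherence
estimators. Directional validity (more adherence, fewer CVD events under
protective effects) uses 50,000 individuals at α = 0.01. These sizes were
chosen so each check's Monte-Carlo error is small against the effect it
verifies.

## Limitations

* All default parameter values are illustrative; conclusions about the
  polypill in any real health system require substituting sourced
  coefficient sets, costs, utilities, case fatalities and a national life
  table (all supported as drop-ins).
* One treatment-effect set serves primary and secondary prevention
  (per-engine overrides are possible but not defaulted).
* No PAD events, renal impairment, falls/fractures, statin myopathy or
  liver dysfunction, or aspirin–cancer effects; no within-hospital pathway
  detail; cardiovascular hospitalisation is folded into the four acute
  types.
* The synthetic population is a structural emulation, not a calibrated
  one; survey weighting and real-data idiosyncrasies are out of scope.
* Costs take an NHS/PSS-style perspective: no productivity or societal
  costs, and no price-year inflation machinery beyond scalar overrides.
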