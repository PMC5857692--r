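# polypillCEA

Individual-level discrete-event simulation (DES) estimating the long-term
cost-effectiveness of a cardiovascular **polypill** strategy (a fixed-dose
combination of aspirin, a statin and two blood-pressure-lowering drugs)
against usual multi-pill care, in an NHS-style setting. It is written for
health economists and modellers who want a fully reproducible, testable
microsimulation: synthetic cohort in, incremental costs and QALYs out.

The motivating question: adherence to multi-drug cardiovascular prevention
is poor, a single combined pill improves it, and the health and cost
consequences of that adherence gain play out over decades — beyond any
trial horizon. The model translates a trial-style adherence effect into
lifetime discounted costs, QALYs, an ICER and net monetary benefit.

## Model core

Each simulated individual *i* carries a risk-factor profile (age, sex,
ethnicity, smoking, SBP, total/HDL cholesterol ratio, BMI, deprivation,
diabetes, prior CVD events, medication). Event risks come from
proportional-hazards risk engines in the QRISK2 functional form

```
P(event by horizon h) = 1 − S₀^exp(β′x)
```

with a primary CVD engine (first TIA/stroke/MI/angina), a REACH-style
secondary engine once CVD is established, and a QDiabetes-style engine for
incident type 2 diabetes. Horizon risks convert to constant hazards
`λ = −log(1−p)/h` between risk-recalculation points (after every event or
every 10 years, the engines' horizon), and lifetime histories are simulated
by competing exponential clocks: composite CVD, diabetes onset, heart
failure, GI bleed, medication cessation and other-cause mortality from a
national-style life table, to death or age 100.

Adherence under usual care is a logistic model on individual
characteristics; the polypill multiplies the adherence probability by a
relative risk (default 1.3, estimable from a two-arm trial dataset by
log-binomial regression), capped at 1. While adherent, treatment modifies
hazards: protective relative risks on CVD (statin x antihypertensive x
aspirin, multiplicative), raised diabetes and GI-bleed risks, a one-shot
ACE-inhibitor cough, and reduced heart failure. Costs and utilities accrue
in continuous time with discounting at 3.5%/yr: `(1+r)^(−t)` for point
costs, `∫c·(1+r)^(−t)dt` for annual flows.

The two arms run under **common random numbers** (per-individual streams
independent of arm), so with all relative risks at 1 the arms are
bit-identical and increments are low-variance otherwise. PSA draws
parameters (lognormal RRs, beta probabilities, gamma costs) and a
population bootstrap per iteration.

## Worked example

```r
library(polypillCEA)

pop <- apply_inclusion(generate_population(population_spec(n = 5000, seed = 42)))
res <- run_cea(pop = pop, master_seed = 42)
print(res)
```

```
Cost-effectiveness results (n = 1648 individuals per arm)
  usual care: £5346, 9.6755 QALYs
  polypill:   £5198, 9.6785 QALYs
  increments: ΔC = £-148.34, ΔE = 0.00301 QALYs
  polypill is dominant (no ratio reported)
  NMB at £20,000/QALY: £208.62
  NMB at £30,000/QALY: £238.76
```

5,000 synthetic adults are generated; 1,648 meet the trial-style inclusion
criteria (established CVD, or a 5-year first-event risk of at least 15%).
Both arms are simulated over the same 1,648 individuals with shared random
streams. Under the packaged illustrative inputs, the polypill arm's higher
adherence averts enough events that it saves money (ΔC < 0) and gains QALYs
(ΔE > 0) — it *dominates* usual care, so no ICER is reported and the
decision summary is the positive net monetary benefit at £20,000 and
£30,000 per QALY. With other inputs the result can be an ordinary ICER;
these illustrative numbers demonstrate the mechanics, not an NHS estimate.

The adherence effect itself can be re-estimated from a synthetic trial:

```r
trial <- simulate_adherence_trial(1000, true_rr = 1.3, seed = 42)
estimate_polypill_rr(trial)
#> Adherence RR (polypill vs usual care): 1.304 (95% CI 1.235-1.376)
```

PSA: `run_psa(pop, psa_spec(n_iterations = 200), default_parameters())`
returns the (ΔC, ΔE) cloud, the cost-effectiveness acceptability curve and
convergence diagnostics; `plot(psa, "plane")` / `plot(psa, "ceac")` draw
them.

A command-line wrapper with `generate-pop`, `run`, `psa`, `sensitivity`
and `validate` subcommands is installed at `inst/cli/polypill-sim.R`.

## Package layout

- `R/population.R` — synthetic cohort generator (Gaussian copula over risk
  factors) and trial inclusion filter
- `R/risk_engines.R` — data-driven proportional-hazards engines and
  risk/hazard conversions
- `R/adherence.R` — adherence classification, logistic usual-care model,
  log-binomial polypill RR, cessation
- `R/treatment_effects.R` — hazard modification per medication class
- `R/des_engine.R` — competing-clock lifetime simulation, case fatality,
  life-table mortality
- `R/economics.R` — discounted cost and QALY accrual
- `R/cea.R`, `R/psa.R` — arms, ICER/NMB, PSA, bootstrap, CEAC, convergence
- `R/parameters.R`, `R/config_io.R` — parameter schema, validation,
  YAML/JSON config, CSV tables, run manifest

The vignette `vignettes/model-methods.Rmd` documents the model's
assumptions, default parameters and limitations.
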