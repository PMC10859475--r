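---
title: "Methods: population PK of tigecycline and dose optimization"
author: "tigeppk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population PK of tigecycline and dose optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tigeppk)
```

## The problem

Tigecycline is a last-resort antibiotic for multidrug-resistant infections in
critically ill patients. Its pharmacokinetics in this population are highly
variable — organ dysfunction, fluid shifts and hypoproteinemia all move drug
exposure — and the efficacy index is AUC(0–24)/MIC, with target ratios that
differ by indication (6.96 for complicated intra-abdominal infection, 12.8
for community-acquired pneumonia, 17.9 for complicated skin and skin
structure infection). `tigeppk` implements a complete population-PK (PPK)
workflow for this setting: structural model, covariate model, mixed-effects
estimation, diagnostics, and Monte Carlo dose optimization, together with a
synthetic cohort generator that emulates an intensive-sampling critical-care
study (98 subjects, 8 samples each around the 7th dose of a q12h 30-min
infusion regimen), so the entire pipeline runs and is tested without
patient-level data.

## Structural model

Disposition is a two-compartment model with first-order elimination and
zero-order infusion input, parameterized by clearance `CL`, central volume
`V1`, intercompartmental clearance `Q` and peripheral volume `V2`. The
central concentration is the closed-form biexponential solution with hybrid
constants `alpha`, `beta` (roots of `s^2 − (k10+k12+k21)s + k10·k21`), with
separate during- and post-infusion branches; multiple doses superpose
because the model is linear in dose. Tests verify the analytic solution
against adaptive-step numerical integration of the ODE system (relative
error below 1e-6), branch continuity at end of infusion, and superposition.

Steady-state AUC(0–24) is available two ways: by explicit superposition of
at least 20 prior doses with dense (0.05 h) linear-up/linear-down
trapezoidal integration over one interval, and by the analytic identity
AUC24 = daily dose / CL. The two agree within 0.5%; superposition is the
default because the study design samples at the 7th dose, which it supports
exactly. The degenerate root case `alpha ≈ beta` (relative gap < 1e-10) is
rejected with an error; it is physiologically precluded for this drug.

## Covariate model

Continuous covariate–parameter relationships use the four conventional
families (with `x = cov/median`): linear `θ_pop + θ_cov·x`, exponential
`θ_pop·exp(θ_cov·x)`, power `θ_pop·x^θ_cov`, and a categorical power form
`θ_pop·θ_cov^cov` for 0/1 covariates. Effects compose NONMEM-style per
parameter: linear terms add to the typical value, the other families
multiply. Creatinine clearance comes from the Cockcroft–Gault equation with
serum creatinine in µmol/L (converted internally to mg/dL by /88.4, since
clinical laboratories here report µmol/L).

The published final model is

```
CL (L/h) = 3.09 + (CCr/77) × 3.28
V1 (L)   = 32.1 × (BW/61)^1.95
Q (L/h)  = 39.7 × (logGGT/1.7)^0.956 × (logTBIL/1.2)^−0.912
V2 (L)   = 113 × (BW/61)^1.61 × (logALB/1.4)^4.52
```

with exponential interindividual variability (IIV) on CL (27.0%), V1
(72.5%) and Q (18.8%) — none estimable on V2 — and a proportional residual
error of 2.02%. Two interpretation decisions were needed:

* **`log` means log10.** The printed normalization constants 1.7, 1.2 and
  1.4 match log10 of the cohort median GGT (53 U/L), TBIL (15.7 µmol/L)
  and ALB (27.9 g/L); natural logarithms do not. Base 10 is the default;
  covariates whose log10 is ≤ 0 raise an error naming the covariate.
* **Normalization constants are stored with the model** (77, 61, 1.7, 1.2,
  1.4), never recomputed from data, so simulation from the published model
  is reproducible bit-for-bit.

Variabilities are standard deviations internally; the conventional percent
reporting (`100·ω`, approximate %CV for exponential/proportional models) is
used in printed summaries, with `sd_to_pct()`/`pct_to_sd()` converting.

## Estimation

The marginal likelihood is approximated FOCE-I-style: a Laplace
approximation at each subject's conditional random-effect mode, with the
residual variance evaluated at the individual predictions (the
"interaction"). Per subject the conditional −2 log-likelihood is

```
g(η) = Σ_j [ ln(2π·var_j) + (y_j − f_j)² / var_j ]  +  ηᵀΩ⁻¹η + ln det(2πΩ),
var_j = σ_add² + σ_prop²·f_j²,
```

and the objective is `OFV = Σ_i [ g(η̂_i) − k·ln 2π + ln det G_i ]` with
`G = JᵀWJ + Ω⁻¹` the Gauss–Newton curvature at the mode. This is the
closest re-implementable analogue of the FOCE-with-interaction method;
exact numerical equality with commercial implementations is not claimed.
The approximation is validated against brute-force adaptive quadrature of
the marginal likelihood on a small one-compartment problem (agreement
within 2 OFV units).

Numerical choices:

* The inner mode search is a damped Newton iteration with the same
  Gauss–Newton curvature, finite-difference Jacobians (step 1e-5), step
  halving, tolerance 1e-8 — always **cold-started at η = 0** so the OFV is
  a deterministic function of data and parameters.
* Predictions are floored at 1e-10 mg/L under proportional error to avoid
  degenerate likelihoods (the design never samples before the first dose,
  so this floor is inactive in practice).
* The outer problem optimizes log-transformed positive parameters
  (structural typical values, categorical effect sizes, ω, σ) and
  untransformed covariate effect sizes; relative tolerance 1e-10.
* The marginal likelihood of covariate exponents on high-IIV parameters is
  **multimodal** (an exponent on V1, which carries 72.5% IIV, can trade
  against the random effects). A single quasi-Newton run from neutral
  starting values can land in a local optimum, so `fit_ppk()` uses a
  deterministic multi-start: the nominal initials plus four jittered
  alternatives (fixed internal seed, caller RNG untouched), a cheap
  pre-search on each, then a full polish of the best basin with restarts
  until the OFV stops improving.
* Default starting values (`generic_initials()`) are deliberately neutral —
  round mid-range structural values, weak covariate effects, 30% IIV, 10%
  residual — detached from the published estimates.
* Relative standard errors come from the inverse Hessian of the OFV at the
  optimum (observed information = Hessian/2), via the delta method for
  log-transformed parameters. `AIC = OFV + 2·(number of estimated
  parameters)`.

## Covariate selection

Candidates are screened for pairwise Spearman correlation first; pairs with
|ρ| above 0.5 (configurable — the underlying analysis states the screen but
no cutoff) may not co-enter a model. Forward inclusion adds, at each step,
the candidate with the largest OFV decrease among those achieving at least
3.84 (χ², p < 0.05, 1 df; ties broken by candidate order and logged);
backward elimination then removes, iteratively, the cheapest effect while
its removal costs no more than 10.83 (p < 0.001), so every retained effect
has a removal cost strictly above 10.83. The threshold semantics ("decrease
of 3.84" read as ≥; retention requires strictly > 10.83) follow the stated
criteria. Candidate fits that fail are skipped and logged, never fatal.

## Diagnostics

`gof_quantities()` returns PRED (population prediction at η = 0), IPRED
(prediction at the empirical Bayes estimates), CWRES (FOCE-linearized
residuals decorrelated by `JΩJᵀ + diag(σ²·IPRED²)`) and TAD (time after
the most recent dose strictly before the observation, so a pre-dose sample
refers to the previous dose). On data simulated under a correctly specified
model, CWRES are calibrated standard-normal (mean within ±0.1, SD within
[0.8, 1.2] at the full design size) — this is asserted in the tests.

`ppk_bootstrap()` resamples subjects with replacement at the original
cohort size (no stratification, matching the analysis design), refits each
resample, and reports per-parameter medians with 2.5/97.5 percentiles;
failed refits are excluded, counted, and the summary is flagged unreliable
above 20% failures. The full analysis uses 1000 resamples; tests use far
fewer, checking the identity resample, percentile ordering and seed
reproducibility instead of full-scale coverage.

`ppk_vpc()` simulates replicate datasets under the design (same subjects,
doses, times, covariates), computes 5th/50th/95th concentration percentiles
per time bin and the 2.5–97.5 envelope of each percentile across
replicates. Default bins are the eight nominal sampling times of the design
(bin edges at midpoints; configurable for other designs). Percentiles are
computed on the raw scale; display is conventionally log-concentration. A
plain (not prediction-corrected) VPC is used, matching the stated method.

## Monte Carlo dose optimization

`simulate_cohort()` draws virtual patients at a covariate stratum: typical
parameters from the final model at the stratum covariates (non-varied
covariates pinned at the cohort medians 77 mL/min, 61 kg, and the log10
medians 1.7/1.2/1.4), individualized with lognormal IIV. `pta()` is the
fraction of patients whose steady-state AUC(0–24)/MIC meets the target;
the AUC is the analytic `daily dose / CL` identity (the trapezoid pipeline
agrees within 0.5% and serves as the cross-check). `pta_grid()` crosses
regimens (50 and 100 mg q12h with loading doses) × MIC (0.125–8 mg/L) ×
strata (CCr 30/80/130 mL/min; body weight 40/60/80/100 kg; liver function
normal/abnormal) × targets, 1000 virtual patients per cell, with per-cell
seeds derived from one master seed; a common-random-numbers mode supports
monotonicity comparisons. `recommend_regimen()` picks the lowest regimen
reaching 90% PTA per cell.

Design decisions here:

* **AUC(0–24) versus per-interval AUC.** The PK/PD index is taken as
  AUC(0–24)/MIC — the standard tigecycline index; the per-interval AUC is
  also exposed (`attr(..., "auc_tau")`) rather than silently hidden.
* **Liver strata.** "Abnormal" means TBIL > 2× or GGT > 3× the upper limit
  of normal; ULNs are not universal constants, so defaults of 21 µmol/L
  (TBIL) and 60 U/L (GGT) are used, configurable, with the abnormal stratum
  placed at 2.5×/3.5× ULN. Because TBIL and GGT enter only Q, liver strata
  leave the PTA unchanged up to Monte Carlo error — asserted in tests.
* **Body-weight strata are decoupled from CCr by default.** In the printed
  equations steady-state AUC depends only on CL, a function of CCr alone,
  so BW strata affect PTA only if BW feeds back into CCr. Whether the
  original simulations did that is not stated; the default keeps the strata
  independent, and `couple_bw_ccr = TRUE` routes the stratum weight through
  Cockcroft–Gault for users who want the coupled behavior.

## Synthetic cohort generator

The generator defines the study conditions: 98 subjects; 92.9% on 50 mg
q12h and 7.1% on 100 mg q12h (daily-dose split of the cohort), as 30-min
infusions with a loading dose of twice the maintenance dose by default (the
label regimen; configurable off); samples immediately before the 7th dose
and 0.5, 1, 2, 3, 4, 6, 12 h after it. Age, body weight and BMI are
truncated normals from the reported mean ± SD and min–max; laboratory
covariates are truncated lognormals moment-matched to the reported median
and interquartile range (`µ = ln median`, `σ = ln(q75/q25)/(2·Φ⁻¹(0.75))`)
— the source reports no distributional forms, so lognormality is a modeling
choice consistent with the skewed, positive labs. Sex is 66.3% male; CCr
derives from Cockcroft–Gault; covariates are static per subject (measured
once). Observations are `f·(1+ε)` with ε re-drawn on the negligible
occasions where `1+ε ≤ 0`. The reported 751 of 784 theoretical records are
emulated by completely-at-random dropout (rate 33/784), off by default.

What the generator does **not** emulate: nonlinear protein binding,
time-varying organ function within the sampling window, informative
dropout, ECMO/renal-replacement subpopulations, or covariate correlations
beyond those induced by Cockcroft–Gault. Passing tests therefore show that
the pipeline recovers a model of this class from data generated under it —
not that the published model is correct for any real patient.

## Validation experiments and problem sizes

* **Simulation–reestimation** (`simulation_reestimation()`): five replicate
  cohorts at the full design size (98 × 8), refitted from neutral initials;
  the median recovered values must match the generating values (structural
  parameters within 15%, covariate effects within 25%, variabilities within
  30%). One fit takes on the order of a minute on a single core.
* **Selection power** (`selection_power_experiment()`): 20 replicates with
  one true effect (BW on V1, exponent 1.95) and one null covariate (ALT).
  This experiment is run scaled down — 32 subjects and 40% IIV on V1 —
  because at the full 72.5% IIV the exponent is weakly identified at small
  n and the experiment would measure design power rather than the stepwise
  machinery; the majority of replicates must select exactly the true set.
* Oracle suites (ODE integration, quadrature, the lognormal closed-form
  PTA, the dose/CL identity) run at small fixed sizes in seconds.

## Known limitations

* FOCE-I is approximated by Laplace with Gauss–Newton curvature; OFV values
  are not numerically interchangeable with other software, and real-data
  OFV/AIC magnitudes are data-specific (the study's raw data are not
  available), so only directions and recovered parameters are validated.
* Ω is diagonal; no interoccasion variability; no η-shrinkage reporting.
* Single covariate exponents on high-IIV parameters are weakly identified
  at n = 98 — individual replicates scatter widely (the bootstrap CIs of
  the source analysis say the same), which is why acceptance works on
  medians across replicate seeds.
* PTA uses total-drug AUC; fAUC/MIC with tigecycline's atypical nonlinear
  protein binding is out of scope.
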