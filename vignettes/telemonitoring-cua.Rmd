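---
title: "Cost-utility microsimulation of heart failure telemonitoring: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-utility microsimulation of heart failure telemonitoring: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hftelesim)
library(dplyr)
```

## The decision problem

Ambulatory heart failure (HF) care in a single-payer system can be augmented
with a nurse-led telemonitoring program: patients take daily weight, blood
pressure and heart-rate readings on a smartphone app, a rule-based algorithm
triages them, and a nurse coordinator responds to alerts. The program incurs
equipment and operational costs but reduces all-cause mortality (relative
risk about 0.81) and all-cause hospitalizations (relative risk about 0.75).
`hftelesim` asks the payer's question: over a patient's remaining lifetime,
what does the program cost per quality-adjusted life year (QALY) gained over
standard clinic-based care?

The package implements a patient-level state-transition model (first-order
Monte Carlo microsimulation) in monthly cycles over a 25-year horizon, with
costs in 2019 Canadian dollars and both costs and QALYs discounted at 1.5%
per year. Every simulated patient is run through the model twice — once per
care arm — on the same random-number stream (common random numbers), so that
arm differences isolate the treatment effects and program costs.

## Model structure

Seven mutually exclusive health states: four community states corresponding
to NYHA functional classes I–IV, two hospitalization states (index admission
and readmission), and absorbing death.

A cycle is one month; a hospitalization occupies exactly one cycle (mean
length of stay is 5.9 days, well under the cycle), and there is no
half-cycle correction — each cycle's cost and utility accrue at the cycle
start's discount factor, `(1 + 0.015)^(-t/12)`.

Within a cycle the occupied state determines accrual, then events resolve in
a fixed order:

1. **Death.** Community states use the patient's own monthly probability
   from the survival layer (times the mortality RR in the telemonitoring
   arm); hospital cycles use the same probability by default, so
   hospitalization moves costs and utility but not mortality. A fixed
   per-cycle in-hospital mortality can be configured instead
   (`inhospital_mortality_monthly`).
2. **Discharge.** Hospital survivors return to the NYHA class they held at
   admission; the model does not prescribe a post-discharge class change.
3. **(Re)admission.** Patients inside the post-discharge *vulnerable phase*
   face the 30-day readmission probability (0.159/cycle); others face their
   NYHA class's monthly hospitalization probability. One admission at most
   per cycle, and a direct hospital-to-hospital transition within a cycle is
   not allowed.
4. **NYHA transition.** Otherwise the class moves by the monthly transition
   matrix, cumulated in column order I→IV.

Cycle utility is the class utility (hospital cycles subtract the 0.059
disutility); cycle cost is the class's monthly cost of living with HF
(emergency department + general practitioner + outpatient + drug components,
the drug component only at ages ≥ 65), plus the mean per-admission cost
(8,908 CAD) in hospital cycles, plus, in the telemonitoring arm, the kit and
operational monthly cost and a one-time amortized site fixed cost
(102,500 / 1,000 patients = 102.50 CAD at entry).

### Design choices in the hospitalization pathway

Three structural points are not determined by the printed inputs; the
package resolves them as follows, and all three are configurable.

* **Vulnerable-phase window** (`readmit_window_months`, default 12). The HF
  literature describes a post-discharge period of elevated rehospitalization
  risk extending from weeks to about a year; the model applies the 30-day
  readmission probability for 12 months after each discharge, renewed at
  every discharge. This keeps lifetime admission intensity proportional to
  the class-specific hospitalization probabilities (a bounded window lets
  class risk re-emerge), while still producing the admission-dominated
  lifetime cost profile typical of HF. Setting the window to 1 restricts
  elevated risk to the first post-discharge cycle; `Inf` makes the elevation
  permanent.
* **Scope of the hospitalization treatment effect**
  (`rr_applies_to_readmission`, default `FALSE`). Daily telemonitoring acts
  on new decompensations — it can prevent an episode from starting — whereas
  30-day readmissions are largely driven by incomplete inpatient treatment
  and discharge coordination, which the program does not touch. The RR
  therefore scales index admissions only; because readmission chains are
  initiated by index events, the effect still propagates to total
  admissions. Setting the flag to `TRUE` scales both probabilities.
* **In-hospital mortality** (`inhospital_mortality_monthly`, default
  `NULL`). With the default, a hospitalized patient faces the same monthly
  death probability as in the community, keeping the mortality treatment
  effect's leverage independent of hospitalization exposure. A fixed
  per-cycle value can be supplied when an external in-hospital mortality
  estimate should dominate.

## Virtual patient generation

Cohorts are synthesized with a Gaussian copula (NORTA-style) sampler: a
latent standard-normal vector with a configurable correlation structure
(Cholesky factorization) is back-transformed per characteristic —

* continuous characteristics as `mean + sd * z` from the reference cohort's
  19 published marginal moments (age 58.23 ± 15.43 years, LVEF
  32.07 ± 13.62%, systolic pressure 110.36 ± 17.91 mmHg, and so on);
* binary characteristics (sex, etiology, five drug classes, defibrillator)
  by latent thresholding at the normal quantile of the published proportion;
* the NYHA class by latent cutpoints placed at the normal quantiles of the
  observed cumulative class counts 44/166/93/1 (of 304), which reproduces
  the class distribution including the rare class IV.

```{r cohort}
params <- tm_parameters()
cohort <- generate_cohort(1000, params, seed = 1)
summarise(cohort,
          age = mean(age_years), female = mean(sex_female),
          lvef = mean(lvef_pct))
table(cohort$nyha_class)
```

Continuous values are clipped to physiological bounds (LVEF to [1, 100],
systolic pressure to [60, 250] mmHg, diuretic dose to [0, 2000] mg/day,
etc.; all configurable). Clipping is rare except for the
furosemide-equivalent dose, whose published mean (99.57) and SD (123.93) put
roughly a fifth of the normal marginal below zero — its generated mean
therefore sits above the published one by construction, which is the price
of combining a normal copula with a nonnegative, highly skewed dose.

The source study's own inter-characteristic correlation matrix is not
published; the package ships a modest, clinically plausible default (older
age with higher systolic pressure, lower ejection fraction with worse NYHA
class and higher diuretic dose, allopurinol with higher urate, and so on)
and accepts any user matrix over the same characteristics, with optional
nearest-correlation-matrix repair for non-positive-semidefinite input.
Consequently the generator emulates the reference cohort's margins and class
mix exactly (up to Monte Carlo error) but only a stand-in for its joint
structure: tests passing on this cohort say nothing about how faithfully the
default correlations reflect any real HF population.

## Survival layer

Each patient receives a lifetime survival curve from a Seattle Heart Failure
Model style proportional-hazards score computed once at baseline:
`h_i = h0 * exp(beta · (x_i - centers))`, converted to a monthly death
probability `1 - exp(-h_i * rr / 12)`. The mortality RR multiplies the
hazard, not the probability, so treated survival is baseline survival to the
power of the RR — a closed-form invariant the tests exploit. Covariates are
not updated during simulation (no aging into the score), matching a
once-per-patient lifetime curve; age does advance for the drug-cost
eligibility gate.

The shipped coefficient set uses published hazard-ratio magnitudes for this
covariate list (about 1.09 per decade of age, 1.03 per 1% lower ejection
fraction, 1.16 per 10 mmHg lower systolic pressure, protective effects for
beta blockade, ACE inhibition, aldosterone blockade and defibrillators, and
an attenuated 1.20 per NYHA class, since ejection fraction, blood pressure
and therapy absorb most of the univariate class effect). Because the exact
coefficient vintage behind any given published analysis varies, the absolute
level is anchored empirically: [calibrate_baseline_hazard()] root-finds the
baseline annual hazard so the standard-care arm accrues a target mean
discounted QALY total (4.95 over 25 years in the reference configuration;
the packaged default 0.1385/year is the calibrated value). Any Cox-style
coefficient set can be swapped in via the config file.

## Economics and outputs

Per-arm discounted costs and QALYs are summarized with Monte Carlo standard
errors (sd/√n); incremental quantities use the paired per-patient
differences, which common random numbers make far tighter than the per-arm
errors. The ICER `ΔC/ΔQ` is always reported together with a dominance
classification, and never as a bare negative number; a zero incremental QALY
yields an explicitly undefined ICER.

```{r reference, eval = FALSE}
ref <- run_reference_case(params, n_patients = 1000, seed = 7)
tidy(ref$cea)    # per-arm costs, QALYs, MCSEs
glance(ref$cea)  # deltas, ICER, classification
```

## Probabilistic sensitivity analysis

Every parameter whose printed "distribution" is not fixed is sampled once
per iteration and held fixed while the cohort is re-simulated (second-order
uncertainty):

* **beta** for utilities, hospitalization and readmission probabilities and
  the hospitalization disutility, parameterized from the printed point
  (taken as the mean) and range (taken as a 95% interval width,
  `sd = width / 3.92`); printed ranges whose point sits at one endpoint are
  used as printed;
* **Dirichlet** per transition-matrix row, with concentrations
  `row × 500` (the effective sample size is not published; 500 reflects a
  large source trial and is configurable), zero cells floored at 1e-6;
* **gamma** by method of moments for the per-admission cost
  (mean 8,908, SD 16,867 — shape ≈ 0.28, a deliberately heavy tail) and for
  the ED, outpatient and drug monthly cost components, whose SDs are implied
  by the published unit-cost SDs at the same utilization; the GP fee is a
  fixed schedule price;
* **log-normal** for both relative risks, `mu = log(point)`,
  `sigma = (log(upper) - log(lower)) / 3.92`.

Sampled probabilities and utilities are clamped to [0, 1]; Dirichlet rows
are renormalized, so every sampled parameter set passes validation. Patient
draws are refreshed each iteration (first-order noise averages out across
the 1000 iterations instead of conditioning the whole analysis on one
realization), and with all-fixed specifications the first iteration
reproduces the deterministic run exactly — the module's oracle. The
hospitalization length of stay (log-normal in the source tables) never
enters accrual, because an admission occupies one fixed cycle, so it is not
sampled. A utilization-count route also exists
(`monthly_cost_from_utilization()` plus `fit_utilization_negbin()`, the
latter a maximum-likelihood negative-binomial fit with a Poisson fallback
for equidispersed counts) for users with raw visit counts; it is not the
default because the published utilization is summarized only by medians.

The cost-effectiveness acceptability curve evaluates, at each
willingness-to-pay λ on a 0–100,000 CAD grid (step 1,000, always including
the conventional 50,000), the fraction of iterations with positive net
monetary benefit `λ·ΔQ − ΔC`.

```{r psa, eval = FALSE}
psa <- run_psa(cohort, params, n_iterations = 1000, seed = 11)
glance(psa)
autoplot(psa)             # cost-utility plane
plot_ceac(ceac(psa))      # acceptability curve
```

## Scenarios

* **NYHA subgroups** (`run_nyha_scenario()`): the full correlated covariate
  generation is kept and only the class assignment is pinned, preserving
  between-patient heterogeneity within the class; the pin flows into the
  class-dependent costs, utilities, hospitalization probabilities and the
  survival score's NYHA covariate. Class IV is refused — a single observed
  class IV patient cannot inform a subgroup.
* **Deployment mixes** (`run_deployment_scenario()`): kit counts follow a
  deterministic largest-remainder allocation of the requested FK:BYOP:BYOE
  ratio, then a seeded shuffle assigns them to patients — allocation noise
  never enters scenario comparisons, and under common random numbers the
  kit mix moves only costs, never QALYs.
* **One-way effectiveness** (`run_oneway()`): a single relative risk is set
  to a bound of its 95% CI and the deterministic case re-run.

## Numerical choices and degenerate inputs

* Probabilities after RR scaling are clamped to 1 with a warning.
* Exactly three uniforms are consumed per patient-cycle whether or not each
  is used, so the compiled engine, the plain-R reference implementation and
  both arms stay draw-aligned; the test suite checks the C++/R agreement
  patient by patient.
* The calibration root-find runs on the log-hazard scale over
  [0.01, 1.5]/year with `uniroot` tolerance 1e-6, reusing one frozen draw
  array across evaluations so the objective is deterministic.
* Transition-matrix validation allows 1e-9 slack on row sums; the printed
  rows sum to exactly 1.
* An empty cohort is an error for simulation; a single-patient cohort
  reports MCSE 0 by convention.
* A non-positive-semidefinite user correlation matrix is an error unless
  nearest-correlation repair is requested, which warns with the Frobenius
  norm of the adjustment.

## Problem sizes and runtime

The reference configuration simulates 1,000 patients × 300 cycles × 2 arms
(well under a second in the compiled engine) and 1,000 PSA iterations
(under a minute). The test suite uses 10⁴–10⁵ draws for moment-recovery
checks and 5,000 counts for the negative-binomial recovery check — sizes at
which the documented tolerances are 3-standard-error bounds.

## Known limitations

* The treatment effects are held constant over the lifetime; nothing decays
  or off-boards patients from the program.
* Quality of life in the telemonitoring arm uses the same state utilities as
  standard care, so any direct QoL benefit of the program is excluded.
* The published source tables for this class of model are not fully mutually
  consistent (their subgroup results do not aggregate exactly to their
  reference case, and their one-way sensitivities imply conflicting
  readmission mechanics), so the package's defaults are one defensible
  resolution, with each contested structure exposed as a parameter rather
  than hard-coded.
* The cohort generator reproduces margins, not the unpublished joint
  distribution; correlation-sensitive downstream quantities (notably the
  survival-score variance, hence the spread of patient-level outcomes)
  inherit that approximation.
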