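---
title: "Emulating a trial of beta blockers after myocardial infarction: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emulating a trial of beta blockers after myocardial infarction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ttemu)
library(data.table)
```

## The scientific problem

Whether long-term beta-blocker therapy still benefits patients who survive
a myocardial infarction (MI) with preserved ejection fraction is an open
clinical question.  An observational analysis can emulate the pragmatic
randomized trial one would like to run — the *target trial* — using
registry data: persons hospitalized for MI with an angiography, assigned
to "beta blockers" or "no beta blockers" according to whether a
prescription was dispensed within 30 days of angiography, and followed
for death and recurrent MI for up to five years.

`ttemu` implements that emulation end to end and pairs it with a
synthetic-registry generator whose causal truth is known, so every step —
eligibility, assignment, adherence, weighting, outcome modelling,
bootstrap, sensitivity analyses — can be validated against an oracle.

## Study design

**Eligibility.**  Six criteria, applied in a declared order: (1) an index
MI hospitalization with angiography within 30 days; (2) no beta-blocker
contraindication (bradycardia, AV block II–III, hypotension, syncope,
asthma, COPD, stroke) in a 3-year lookback; (3) no beta-blocker
indication other than secondary prevention, operationalized as prior
beta-blocker use (dispensation history and/or admission record), heart
rate ≥ 120, systolic blood pressure ≥ 180, diastolic blood pressure
≥ 120, or a history of chronic heart failure or atrial flicker/flutter;
(4) no psychiatric disorder or dementia in the lookback; (5) statins and
antithrombotics dispensed at or before time zero; (6) no death or MI
during the assignment window.  Each criterion's pass set is computed
independently, so the final cohort is invariant to the order while the
flowchart counts are not.

**Time zero and assignment.**  Time zero is angiography + 30 days for
*both* arms (a landmark design), with window events excluded.  Whether
follow-up should instead start at angiography or at prescription is
genuinely ambiguous; the landmark reading makes the alignment explicit
and testable, and the clone-censor sensitivity analysis (below)
quantifies what the choice costs.  A same-day dispensation counts as
prior use, a dispensation strictly after angiography as assignment.  A
discharge record of beta-blocker therapy without a dispensation assigns
the person at the discharge date (modelled as angiography + 3 days in
the generator).

**Adherence.**  Each dispensation's intended duration is
`floor(pill_count × pill_dose / daily_dose)` days, with the daily dose
assumed 100 mg for metoprolol and 5 mg for bisoprolol.  Early refills
stockpile (coverage extends from the end of the previous dispensation);
the alternative restart-at-dispense convention is available by flag.  In
the beta-blocker arm a person deviates at the first refill gap of 180
days or more (90 in a sensitivity analysis), *including* exhaustion of
coverage; the censor date is coverage end + gap, the first day the gap
criterion is violated — the rule itself only defines the gap, so the
censor-date convention is ours and is configurable.  A contraindication
diagnosis on or before the coverage end excuses the gap.  In the
no-beta-blocker arm a person deviates at the first beta-blocker
dispensation after time zero unless a new indication (hypertension,
angina, arrhythmia, heart failure) was diagnosed on or before that date.

**Discrete time.**  Follow-up is discretized into 30.4375-day "months",
60 per five years.  An event closes its interval; a person censored
mid-interval contributes only complete intervals (discrete-time hazard
models need whole at-risk intervals, so partially observed intervals are
dropped rather than fractionally weighted).  Whether a partially covered
interval should count as adherent is unstated in the design we emulate;
the floor convention is our choice.  With the MI outcome we estimate the
*total effect*: death does not end follow-up — the person contributes
MI-free intervals until the administrative end, yielding a
cumulative-incidence-type risk.

**Weighting.**  Baseline confounding is adjusted by stabilized inverse
probability of treatment weights from a logistic assignment model;
per-protocol selection bias by time-varying inverse probability of
censoring weights estimated per arm with pooled logistic models whose
denominator conditions on baseline covariates, the time-varying
covariates (renal-disease onset; dispensation of ARBs, ACE inhibitors,
calcium-channel blockers, diuretics, nitrates, diabetes treatment) and a
restricted cubic spline of time, and whose numerator omits the
time-varying covariates.  The combined per-interval weight is the
product.  Stabilization is our choice (the source protocol describes the
denominator only informally); unstabilized per-protocol weights are too
variable to be usable.  Weight truncation is off by default, with a
percentile option, because the emulated protocol never truncates.  In
the total-effect MI data a person's censoring weight is carried forward
after death, when deviation is no longer possible.

**Outcome model.**  A pooled logistic discrete-time hazard model: event
indicator on strategy, a restricted cubic spline of follow-up time with
knots at 6, 12, 24 and 48 months, and the full strategy-by-time product
term.  Risks follow the product-limit recursion
`risk(t) = 1 − Π(1 − hazard(s))`; the 5-year risks are contrasted as a
difference and a ratio.  The average hazard ratio at 3, 4 and 5 years is
`exp` of the strategy coefficient from a refit *without* the product
term on person-time truncated at that horizon — refitting, not
integrating the 5-year fit, so each horizon's estimate uses exactly the
person-time it claims to.  When baseline covariates enter the outcome
model instead of weights (sensitivity 1), risks are standardized by
averaging per-subject predicted risk curves over the cohort (parametric
g-formula).

**Inference.**  Nonparametric bootstrap (500 samples at paper scale),
resampling persons with all their records; percentile 2.5/97.5
intervals.  Weight models are re-estimated inside every replicate, so
their estimation uncertainty propagates.  Resampling is implemented as
multinomial frequency weights fanned through every fit, which keeps the
person-interval expansion fixed and makes a replicate cheap.

## The synthetic registry and its oracle

The generator emulates the statistical structure the analysis assumes:

* covariates (12 by default: age, sex, smoking, hypertension, diabetes,
  previous MI, heart-failure history, infarction type, heart rate,
  systolic blood pressure, LDL, creatinine) with marginals loosely
  calibrated to a Swedish post-MI population — the full ~40-covariate
  set of a real registry is accepted via `covariate_spec` but not
  defaulted, because the exact categorizations are not public;
* confounded prescribing: a logistic assignment model on (standardized)
  covariates, defaulting to ~89% prescribed;
* discrete-time death and MI hazards with per-covariate log odds and a
  configurable conditional treatment effect, simulated on the analysis
  grid itself.  An interval index is materialized as the calendar day at
  the *interval midpoint*, which round-trips exactly through the
  interval mapping (an end-of-interval date would land in the next
  interval and break the grid);
* refill sequences (90/100 pills at 50/100 mg metoprolol or 5 mg
  bisoprolol, refill delay −10..40 days) with informative
  discontinuation and crossover processes whose default intercepts are
  calibrated so arm-specific adherence lands near 74% and 91% — the
  values a Swedish post-MI population exhibits — with contraindication
  and new-indication diagnoses emitted before a configurable fraction of
  deviations so both override branches of the adherence rule are
  exercised;
* prior beta-blocker use emitted both as lookback dispensations and as
  an admission-record flag with imperfect (90%) agreement, supporting
  the prior-use sensitivity variants;
* statin/antithrombotic co-treatment in 94% of persons; missingness in
  LDL (15.5%) and creatinine (4.4%).

`compute_true_effects()` simulates, for each oracle person, both
counterfactual histories (always treated, never treated) from the same
event model with adherence forced perfect, using common random numbers
across arms, and reports marginal risks per interval with binomial
Monte-Carlo standard errors.  Parameter-recovery tests compare pipeline
estimates against this truth.

What the generator does **not** emulate: real ICD-10/ATC coding,
hospital clustering, migration, dose tapering, or continuous-time event
dates.  Passing tests therefore show the *estimators* are correct under
the assumed structure, not that the assumptions hold in any real
registry.

## Sensitivity analyses

The grid always contains the main ITT and per-protocol analyses plus:

1. baseline covariates in the outcome model instead of IP weights, with
   g-formula standardization;
2. prior-beta-blocker variants: (2a) prior users eligible, prior-use
   indicator added to the weight model; (2b) exclusion from the
   admission record only, dispensation-history indicator added;
3. missing-data variants: (3a) complete case, (3b) continuous covariates
   categorized into quintiles with a "missing" level;
4. a clone-censor-weight analysis of baseline alignment: time zero at
   angiography, every eligible person cloned into both arms, the
   beta-blocker clone censored at 30 days without initiation, the
   no-beta-blocker clone at the first dispensation, with grace-window
   censoring weights estimated per arm from baseline covariates, and
   window events counted;
5. the 90-day per-protocol gap.

The clone-censor recipe deserves a caveat: its authoritative
specification is not public, so the implementation here is the standard
clone-censor-weight construction with every modelling choice mirroring
the main analysis.  Clone follow-up runs one grace interval past the
usual horizon so that its risk horizon spans the same five years as the
landmark analysis.  For the alignment *equivalence* check we use
saturated-time unweighted fits: with immediate initiation and no window
events the clone hazards equal the landmark hazards interval for
interval and the risks agree to machine precision, whereas two spline
fits of different datasets (the clone data contain an extra event-free
grace interval) could never agree to that tolerance.  Eligibility for
cloning drops the two criteria that are unobservable at angiography
(statin/antithrombotic by day 30; event-free window) — conditioning on
them would condition on the future, which is exactly what cloning
exists to avoid.

## Numerical choices and degenerate inputs

* Saturated-time fits are computed analytically as weighted per-(arm,
  interval) event proportions — the exact logistic MLE on the saturated
  design.  This is what makes the Kaplan–Meier equivalence hold to
  1e-10 rather than to glm convergence tolerance.
* The restricted cubic spline uses the standard truncated-power
  construction with scaling `(k_K − k_1)²`, implemented directly; it is
  exactly zero-nonlinear below the first knot and linear above the last.
* Logistic fits flag non-convergence and separation (|coef| > 15); the
  treatment model errors, while censoring-weight models warn and
  proceed, since a rare-censoring arm with many covariates can be
  legitimately unstable and the weights are bounded by later truncation
  if requested.  An arm with zero censoring events gets weights 1 with a
  message.
* Ties: a same-day death and MI counts as MI for the MI outcome, death
  for the death outcome, one event for the composite.  An event on the
  same day as a censor date wins (events close their interval).
* Zero-person configurations produce empty tables, not errors; a grace
  period nobody can meet produces an informative error.

## Problem sizes

Validation runs use cohorts of 2,000–50,000 synthetic persons: 20,000
for the confounding-null and balance checks, 50,000 (with a 50,000-person
oracle) for effect recovery, 200 simulation replicates of n = 2,000 with
200 bootstrap samples for CI coverage, and 500-person-scale fixtures for
exact arithmetic.  These sizes put Monte-Carlo error well inside the
tolerances being asserted while keeping a full run of the suite on one
CPU comfortable.  The coverage study uses the nonparametric
(saturated-time) IPW risk estimator inside the bootstrap, which is the
same estimand with far less per-replicate cost than the spline fit.

## Known limitations

* The generator's event hazards are piecewise-constant on the month
  grid; continuous-time refinements (within-interval ordering beyond the
  tie rules) are not modelled.
* Censoring-weight models include spline time and are fit per arm;
  whether the emulated protocol's models included time or arm
  interactions is unstated, so this choice is kept visible here rather
  than buried.
* Standardized risk curves report the mean conditional hazard alongside
  the (correct) standardized risk; the two are consistent only for the
  risk scale.
* In the total-effect MI analysis, post-death person-intervals remain in
  the censoring-weight risk set (with carried-forward weights); the
  alternative — dropping them from the censoring models — changes
  weights negligibly in the regimes tested but is not implemented.
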