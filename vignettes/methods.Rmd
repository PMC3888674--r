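---
title: "Methods: simulated antipsychotic cohorts and their analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated antipsychotic cohorts and their analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(apcohort)
```

`apcohort` implements a complete pharmacoepidemiologic cohort analysis of
antipsychotic exposure and cardiac outcomes, together with the synthetic
linked-record generator used to validate it. This vignette documents the
models, the conventions, the tunable parameters, and the design decisions
taken where more than one reasonable choice existed.

## Calendar and interval conventions

All dates are day offsets from a run origin, and all intervals are
half-open `[start, end)`. One month is 30.4 days, six months 182.4 days,
one year 365.25 days, three weeks 21 days. These constants propagate into
every rule that mentions them (the prescription grace period, the recency
window, the free-text window), so person-time arithmetic is exact rather
than calendar-approximate.

## The synthetic-record generator

The generator emulates four linked record streams of a UK-style
primary-care research database: a patient registry (practice, sex, birth
year, registration and collection dates, transfer-out), prescriptions
(drug, class, quantity, prescribed daily dose, tablet strength),
coded events from three independently collected sources (primary-care
Read-like codes, hospital episodes with admission/discharge dates and
ICD-10-like diagnoses, death certificates), and short free-text notes near
death dates carrying a held-out truth label.

Outcome event times are drawn from piecewise-constant hazards by
inversion: each generator cause (sudden cardiac death, other cardiac
death, other mortality, suicide, plus nonfatal CHD and ventricular
arrhythmia processes) has a baseline rate per person-year, multiplied per
patient by sex (log hazard ratio 0.15 for men), psychiatric status (0.4)
and any configured confounder effects, multiplied by an attained-age step
function (log hazard ratio 0.45 per decade above 60, stepping at the
ten-year age-band birthdays, so hazards rise as patients age during
follow-up), and multiplied during *current* antipsychotic exposure by the
planted rate ratios, including optional dose-band multipliers. Death
terminates follow-up; the four death causes compete through their summed
hazard, the cause being sampled from the hazard mix active in the death
segment. Aligning the generator's age steps with the models' default
ten-year adjustment bands makes the banded Poisson adjustment correctly
specified, which keeps the null calibration of the Wald interval nominal;
an age effect frozen at entry would instead leave frailty that
time-varying age bands cannot absorb.

Defaults were chosen once to be realistic for this population and are not
revisited: baseline mortality of roughly 26 per 1000 person-years in
psychiatric nonusers (dominated by non-cardiac causes, with sudden cardiac
death at 2 per 1000), psychiatric prevalence near 16% (major depression
10%, dementia 3.5%, schizophrenia and bipolar disorder about 1% each),
50% of psychiatric patients treated, 60% of prescriptions typical, 30% of
users prevalent at entry, a skewed dose mix (60/25/15 across the
low/medium/high chlorpromazine-equivalent bands), around twenty repeat
prescriptions per user with gaps mostly inside the 30.4-day grace window,
and missingness of 20% for BMI, 15% for smoking and 2% per prescription
field.

What the generator does *not* emulate matters for interpretation: real
Read/Multilex dictionaries (compact stand-in code sets are used), secular
prescribing trends, within-patient dose titration beyond drug switches,
depot injections, and miscoded or free-text-only deaths beyond the
templated notes. Passing tests therefore demonstrate that the pipeline's
algebra and estimators are correct under a known data-generating process —
not that any clinical estimate from real records would be unbiased.

## Exposure model

The defined daily dose is `prescribed_daily_dose × strength`, converted to
chlorpromazine equivalents with a per-drug factor table. The factors are
package defaults assembled from published consensus equivalence tables and
are overridable; they are deliberately *not* presented as a reproduction
of any specific source. Converted doses outside 25–1000 mg/day are treated
as unknown, as are durations (`quantity / prescribed_daily_dose`) outside
1–91.4 days; both are imputed with the median of calculable values for the
same product (drug and strength), falling back to the drug substance and
then broader levels, with flags kept. Imputation is idempotent: re-running
it on its own output changes nothing.

Current exposure runs from a prescription start to 30.4 days after the
expected end of treatment; a repeat within that window (boundary
inclusive) extends the same treatment window. Recent exposure ends 182.4
days after the expected end of treatment — measured from the expected end
by default; a configuration flag (`recent_from = "current_end"`) supports
the alternative reading measured from the end of the grace window. Within
current windows, sub-segments carry the active dose band (doses of
concurrent prescriptions are summed; through grace gaps the last active
dose is carried forward), the running cumulative-treated-duration band,
and the active drug class (`mixed` when typical and atypical overlap;
recent and past intervals inherit the class mix of the whole preceding
treatment window). Timeline correctness is established against an
independent brute-force oracle that classifies half-day-spaced time points
by scanning every prescription; band labels are evaluated at segment
midpoints, since band-threshold crossings are themselves segment
boundaries and a midpoint is strictly inside its band (evaluating at the
boundary would be one floating-point ulp from the threshold).

## Cohorts and matching

Users are indexed at their first prescription under observation;
prescriptions predating the patient's collection start make them prevalent
rather than incident. Controls are matched 1:3 on practice, sex and birth
year within ±2 years (the tolerance is a package default — exact calendar
matching is implied by assigning the user's index date to the control, and
the age tolerance is configurable); the control's inherited index date
must fall at least 12 months after the start of that patient's data
collection. Users with fewer than three eligible controls keep what
exists and are flagged. A control later prescribed antipsychotics is
censored at that prescription, mirroring the psychiatric-nonuser censoring
rule. The psychiatric-nonuser cohort is unmatched, indexed at first
diagnosis, and requires no antipsychotic prescription before that
diagnosis. Exclusions (congenital conduction disorders or advanced
cardiomyopathy at any time; the ventricular-tachyarrhythmia set on or
before registration and again on or before the index date) are applied
after matching, and controls orphaned by an excluded user are removed,
with per-rule counts logged.

## Adjudication

Case ascertainment applies a strict source hierarchy: death certificate,
then free text, then primary-care code; the event date is the recorded
death date for certificates, and otherwise the earliest of the death date,
note date and code date as applicable. The narrow SCD definition excludes
deaths within 30 days after a hospital discharge (in-hospital deaths also
disqualify); the broad definition's phrase "a record of hospitalisation"
is ambiguous, so both readings are implemented — an episode overlapping
the 30 days before death (default) or any episode during follow-up — and
neither is asserted as the intended one. The primary-care-only tier
requires a primary-care record of a broad-set code near the death; free
text alone does not satisfy it. ICD-10-like codes match hierarchically
(an entry matches every code it prefixes once dots are removed), and the
Read-like stand-ins inherit the same semantics. The broad code set keeps
the whole R96 block so that the narrow set is nested inside it on code
grounds.

The free-text "review" is a deterministic rule engine: a note matches if
all substrings of any trigger phrase occur (case-insensitively), and the
verdict is `scd` unless a configured exclusion phrase — another clearly
specified cause of death such as a motor vehicle accident or an overdose —
appears. The human two-reviewer protocol this replaces cannot be
reproduced in code; the packaged exclusion-phrase list is editable
configuration, and a ~30-subject hand-crafted fixture
(`adjudication_fixture()`) pins every rule, one subject per rule.

## Rate estimation

Person-time is accumulated into cells split at every stratum boundary:
exposure-state changes, age-band birthdays (ten-year bands by default,
configurable; coarser bands such as <30/30–64/65–79/≥80 suit stratified
reporting), and dose or cumulative-duration changes. User
follow-up is restricted to current exposure for the primary comparisons.
Rates are modelled with Poisson regression on the aggregated cells with a
log person-years offset — for this model family cell-level and
subject-segment-level fits give identical estimates, which the closed-form
crude-ratio oracle verifies to better than six significant figures.
Fitting uses iteratively reweighted least squares (`stats::glm`) with a
deviance tolerance of 1e-10 and up to 100 iterations; no overdispersion
correction is applied. Contrasts with zero events in either arm are
reported as not calculable (NC) rather than fitted.

Full adjustment applies backward elimination: the candidate pool (in
deterministic alphabetical order) is first truncated so non-forced
parameters stay within one per five outcome events; candidates with joint
Wald P ≥ 0.10 are then removed iteratively, and only those with P < 0.05
are retained. Age bands, sex and the exposure contrast are always kept.
Categorical covariates are tested jointly on their full coefficient block;
missing BMI and smoking values enter as explicit `missing` factor levels.

## Hazard smoothing

Follow-up from treatment start is divided into 100 equal periods, and
per-period rates (events over at-risk person-time — the rate analogue of
Nelson–Aalen increments) are smoothed with a kernel. The kernel is
Epanechnikov with a default bandwidth of five period widths, both
configurable; weights are normalised to sum to one at every evaluation
point, so a constant hazard is reproduced without boundary shrinkage, and
points within one bandwidth of either end are flagged as boundary
estimates. Pointwise variance treats period counts as Poisson; intervals
are normal-theory on the log scale, as is the confidence band of the
ratio of two curves, which is masked wherever the denominator is zero.

## Validation experiments and their design

The acceptance suite's simulation experiments were sized by power
calculations *before* being run, and their settings are part of the
experimental design rather than generator defaults:

* **Null calibration.** 200 replicate pipelines at n = 20,000 under the
  null; the age/sex-adjusted 95% interval for current use versus
  psychiatric nonusers should exclude 1 in about 5% of runs. With ~90
  exposed and ~250 reference events per replicate the Wald interval is
  close to nominal.
* **Confounded recovery.** A strong confounder (log odds +2.0 on
  treatment, log hazard +1.5 on mortality, planted on the
  prior-psychiatric-admission flag) with true current-use rate ratios of
  0.5, 2 and 4 at n = 50,000. Fully adjusted estimates are required to
  have |log bias| < 0.05 per rate ratio (16/10/10 replicates give
  Monte-Carlo standard errors of 0.02–0.015). The crude bias is about
  +0.19 on the log scale at a true ratio of 0.5 but shrinks toward zero at
  4: at high planted hazards the confounder-positive users are selectively
  depleted during current exposure, which erodes the person-time imbalance
  that carries the confounding — a real phenomenon of current-use
  comparisons, not an estimator artefact. The planted direction is
  therefore asserted on the mean across the three rate ratios.
* **Dose-response monotonicity.** Planted dose multipliers 1.5/2/2.5 with
  a balanced dose mix, sustained prescribing (about 40 repeats) and
  n = 80,000 per replicate give roughly 200/280/400 events across the
  bands, adjacent-pair z-statistics near 3, and a per-replicate
  monotone-recovery probability of about 0.997, so 50 replicates clear the
  95% requirement with margin. A skewed real-world dose mix would leave
  the adjacent-band contrasts underpowered at any feasible n; the
  balanced mix is the appropriate designed experiment for the question
  "does the estimator recover a monotone gradient".
* **Smoother recovery.** A constant hazard of 0.12/year, 20,000 subjects
  and a 15-period bandwidth: a constant hazard has no smoothing bias, so
  the wide window is the right design for a tight (±10%) pointwise check;
  the observed maximum relative error is about 2%.

## Known limitations

Covariate effects on hazards are fixed at entry (age does not accrue
during follow-up), psychiatric disease raises mortality uniformly across
the four diagnoses, and adherence equals prescription coverage. The
free-text generator produces templated sentences, so the search's perfect
recall on simulated notes says nothing about recall on real clinical
text. The matching step allows a control to serve several users (sampling
is without replacement within a match group only). None of these
limitations affect the algebraic layers, which are checked exactly against
independent oracles.
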