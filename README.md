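# apcohort

Antipsychotic drugs have repeatedly been associated with excess mortality
and sudden cardiac death (SCD), but database studies of the question are
hard to get right: exposure must be reconstructed from prescription
records, SCD is notoriously difficult to ascertain from routine codes, and
people prescribed antipsychotics differ systematically from people who are
not (confounding by indication). `apcohort` implements the full analysis
pipeline of a UK primary-care cohort study of these questions — and,
because the real records are proprietary, it ships a synthetic linked-record
generator with *known* treatment effects, so every stage of the pipeline can
be validated against a planted truth.

The package is aimed at pharmacoepidemiologists and methods researchers who
want a tested, reusable implementation of this class of study design.

## What it implements

* **Synthetic linked EHR** (`sim_config()`, `simulate_ehr()`): patient
  registry, prescriptions, coded events from three sources (primary care,
  hospital episodes, death certificates) and free-text notes near deaths.
  Event times are drawn from piecewise-constant hazards; during *current*
  antipsychotic exposure each cause-specific hazard is multiplied by
  configurable rate ratios (overall, by dose band), and covariates can be
  given effects on both treatment odds and outcome hazards to plant
  confounding.
* **Cohorts** (`identify_users()`, `match_controls()`,
  `identify_psych_nonusers()`, `apply_exclusions()`): incident/prevalent
  antipsychotic users indexed at first observed prescription; 1:3
  general-population controls matched on practice, sex, birth year (±2
  years) and calendar time; an unmatched psychiatric-nonuser cohort indexed
  at first diagnosis and censored at any later antipsychotic prescription;
  cardiac exclusion rules with a flow log.
* **Exposure** (`prepare_episodes()`, `build_timelines()`): prescribed
  daily dose × tablet strength converted to chlorpromazine-equivalent
  defined daily doses (valid range 25–1000 mg/day), durations as
  quantity/daily dose (valid 1–91.4 days), both with two-level median
  imputation; prescriptions stitched into *current* (up to one month —
  30.4 days — after the expected end of treatment), *recent* (until six
  months after) and *past* exposure, with dose-band (<200 / 200–399 /
  ≥400 mg) and cumulative-duration (<1 / 1–3 / >3 years) sub-segments.
* **Outcome adjudication** (`search_free_text()`,
  `adjudicate_outcomes()`): case-insensitive trigger-string search of free
  text within ±3 weeks of death (restricted to practices with above-median
  text volume, from a configurable start year), a source-precedence
  hierarchy (death certificate → free text → primary-care code) with
  earliest-date resolution, suicide exclusion from all-cause mortality, and
  three nested SCD definitions — the narrow one excluding deaths within 30
  days of a hospital discharge, the broad (Ray-style) one with a
  configurable hospitalisation exclusion, and a primary-care-only tier.
* **Rates** (`accumulate_person_time()`, `fit_rate_ratio()`,
  `select_covariates()`, `stratified_rr()`): person-time split at exposure
  and age-band boundaries (user follow-up restricted to current exposure),
  Poisson regression with log person-years offset, and backward covariate
  elimination under a five-events-per-parameter budget (retention at
  P < 0.05, removal at P ≥ 0.10, missing-indicator levels for BMI and
  smoking). Inestimable contrasts are reported as NC, not errors.
* **Hazard curves** (`build_hazard_grid()`, `smooth_hazard()`,
  `hazard_ratio_curve()`): follow-up from treatment start divided into 100
  equal periods, per-period rates kernel-smoothed (Epanechnikov), and
  pointwise ratio curves with log-scale confidence bands.

## Worked example

The `analysis/` scripts run the whole study on a generated population
(50,000 patients, ten years of follow-up) in which current antipsychotic
exposure multiplies every death cause by a planted factor of **1.75** while
the nonfatal outcomes are null:

```sh
Rscript analysis/01_simulate.R      # writes results/ehr/*.csv
Rscript analysis/02_cohorts.R       # users, matched controls, nonusers
Rscript analysis/03_exposure.R      # DDD standardisation + timelines
Rscript analysis/04_outcomes.R      # free-text search + adjudication
Rscript analysis/05_rates.R         # person-time + Poisson rate ratios
Rscript analysis/06_hazard_curves.R # smoothed hazard-ratio curves
```

Stage 5 prints, among other tables, the fully adjusted rate ratios for
current use versus psychiatric nonusers (planted truth 1.75 for the
mortality outcomes, 1.0 for CHD and ventricular arrhythmia):

```
                  outcome    rr ci_low ci_high events_exposed
1:    all_cause_mortality  1.76   1.56    1.98            439
2:      cardiac_mortality  1.61   1.27    2.04            105
3:            scd_primary  1.68   1.04    2.71             26
4:          scd_secondary  1.64   1.27    2.11             93
5:           scd_tertiary  1.52   1.05    2.20             43
6:                    chd  1.09   0.75    1.57             39
7: ventricular_arrhythmia  0.98   0.55    1.75             15
```

Every mortality outcome covers the planted 1.75 (the headline all-cause
estimate lands on 1.76), the nonfatal outcomes cover their planted null,
and the three SCD tiers — with only 26–93 exposed cases — show the wide
intervals that motivate reporting nested definitions in the first place.
The companion comparison against matched
general-population controls over-estimates the same planted effect, because
psychiatric illness itself carries excess mortality in the generator: that
gap is the confounding-by-indication signal this design exists to expose.
Stage 6 writes the smoothed atypical-versus-typical mortality-ratio curve
over treatment time (`results/hazard_ratio_curve.csv`, with an optional
PDF).

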