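#' Simulation configuration
#'
#' Defines the synthetic-data generating process: a primary-care population
#' with linked hospital and death-registry records, psychiatric diagnoses,
#' antipsychotic prescribing, and outcome events drawn from piecewise-constant
#' hazards in which the planted rate ratios apply during current antipsychotic
#' exposure. All dates are day offsets from `origin_date`.
#'
#' `true_rr` holds multiplicative rate ratios applied during current exposure:
#' `all_cause_mortality` scales every death cause, `cardiac_mortality`
#' additionally scales the cardiac causes, `scd` additionally scales sudden
#' cardiac death, and `chd` / `ventricular_arrhythmia` scale the nonfatal
#' event processes. `dose_rr` adds a further multiplier by the active
#' chlorpromazine-equivalent dose band, used to plant dose-response gradients.
#'
#' `confounder_effects` is a named list of per-covariate effect pairs
#' `c(treat = log-odds shift on treatment assignment, outcome = log hazard
#' ratio on the death causes)`; covariate names must be among
#' `alcohol_drug_abuse`, `diabetes`, `suicide_attempt`,
#' `prior_psych_admission`, `smoking_current`.
#'
#' @param n_patients,n_practices population size and number of practices.
#' @param origin_date calendar date of day offset 0.
#' @param horizon_years length of the data-collection window in years.
#' @param seed integer seed; identical configurations (including seed)
#'   reproduce byte-identical tables.
#' @param true_rr named list/vector of planted current-exposure rate ratios.
#' @param dose_rr named vector `c(low=, medium=, high=)` of extra
#'   current-exposure multipliers by active dose band.
#' @param baseline_hazards events per person-year in the unexposed reference
#'   for each generator cause (`scd`, `cardiac_other`, `other_mortality`,
#'   `suicide`, `chd`, `ventricular_arrhythmia`).
#' @param confounder_effects see Details.
#' @param psych_prevalence named probabilities of ever-recorded diagnosis for
#'   schizophrenia, bipolar, major_depression, dementia.
#' @param treatment_given_psych probability that a psychiatric patient is
#'   prescribed antipsychotics (before confounder shifts).
#' @param typical_fraction probability that a prescription episode uses a
#'   typical (first-generation) drug.
#' @param prevalent_fraction fraction of treated patients given an
#'   antipsychotic prescription predating their data-collection start, making
#'   them prevalent rather than incident users.
#' @param dose_band_probs patient-level target dose band mix.
#' @param mean_rx_count mean number of repeat prescriptions per treated
#'   patient.
#' @param rx_gap_profile probabilities that the gap to the next prescription
#'   (measured from the expected end of the previous one) is within the
#'   30.4-day grace period (`continuous`), a 1-6 month break
#'   (`recent_break`), or longer (`long_break`).
#' @param missing_rates fraction of values set missing for `bmi`, `smoking`,
#'   and the prescription fields `quantity`, `prescribed_daily_dose`,
#'   `strength` (exercising downstream imputation).
#' @param age_log_hr_per_decade,male_log_hr,psych_log_hr log hazard ratios on
#'   the death causes for age (per decade above 60), male sex, and
#'   any recorded psychiatric diagnosis.
#' @param hospitalised_death_fraction fraction of deaths preceded by a
#'   hospital episode ending shortly before death (exercises the 30-day
#'   discharge rule of the narrow sudden-cardiac-death definition).
#' @param scd_read_code_prob probability that a sudden cardiac death also
#'   receives a primary-care code; `cardiac_read_code_prob` likewise for
#'   other cardiac deaths.
#' @param cardiac_read_code_prob see above.
#' @param free_text_note_prob probability that a death generates a free-text
#'   note near the death date.
#' @param free_text_start_year calendar year from which free text is usable.
#' @param background_admission_rate hospital admissions per person-year
#'   unrelated to outcomes.
#' @param exclusion_condition_rate probability of carrying a code from the
#'   packaged exclusion-condition sets.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 20000L,
                       n_practices = 40L,
                       origin_date = "2000-01-01",
                       horizon_years = 10,
                       seed = 1L,
                       true_rr = list(),
                       dose_rr = c(low = 1, medium = 1, high = 1),
                       baseline_hazards = list(),
                       confounder_effects = list(),
                       psych_prevalence = c(schizophrenia = 0.012,
                                            bipolar = 0.012,
                                            major_depression = 0.10,
                                            dementia = 0.035),
                       treatment_given_psych = 0.5,
                       typical_fraction = 0.6,
                       prevalent_fraction = 0.3,
                       dose_band_probs = c(low = 0.6, medium = 0.25,
                                           high = 0.15),
                       mean_rx_count = 20,
                       rx_gap_profile = c(continuous = 0.85,
                                          recent_break = 0.09,
                                          long_break = 0.06),
                       missing_rates = c(bmi = 0.2, smoking = 0.15,
                                         quantity = 0.02,
                                         prescribed_daily_dose = 0.02,
                                         strength = 0.02),
                       age_log_hr_per_decade = 0.45,
                       male_log_hr = 0.15,
                       psych_log_hr = 0.4,
                       hospitalised_death_fraction = 0.25,
                       scd_read_code_prob = 0.6,
                       cardiac_read_code_prob = 0.4,
                       free_text_note_prob = 0.6,
                       free_text_start_year = 2006L,
                       background_admission_rate = 0.04,
                       exclusion_condition_rate = 0.004) {
  rr_def <- list(all_cause_mortality = 1, cardiac_mortality = 1, scd = 1,
                 chd = 1, ventricular_arrhythmia = 1)
  true_rr <- utils::modifyList(rr_def, as.list(true_rr))
  # reference (unexposed, psychiatric) rates: overall mortality around
  # 25/1000 person-years, dominated by non-cardiac causes
  bh_def <- list(scd = 0.002, cardiac_other = 0.0045,
                 other_mortality = 0.019, suicide = 0.0008,
                 chd = 0.0035, ventricular_arrhythmia = 0.0018)
  baseline_hazards <- utils::modifyList(bh_def, as.list(baseline_hazards))

  cfg <- list(
    n_patients = as.integer(n_patients), n_practices = as.integer(n_practices),
    origin_date = as.Date(origin_date), horizon_years = horizon_years,
    seed = as.integer(seed), true_rr = true_rr, dose_rr = dose_rr,
    baseline_hazards = baseline_hazards,
    confounder_effects = confounder_effects,
    psych_prevalence = psych_prevalence,
    treatment_given_psych = treatment_given_psych,
    typical_fraction = typical_fraction,
    prevalent_fraction = prevalent_fraction,
    dose_band_probs = dose_band_probs / sum(dose_band_probs),
    mean_rx_count = mean_rx_count,
    rx_gap_profile = rx_gap_profile / sum(rx_gap_profile),
    missing_rates = missing_rates,
    age_log_hr_per_decade = age_log_hr_per_decade,
    male_log_hr = male_log_hr, psych_log_hr = psych_log_hr,
    hospitalised_death_fraction = hospitalised_death_fraction,
    scd_read_code_prob = scd_read_code_prob,
    cardiac_read_code_prob = cardiac_read_code_prob,
    free_text_note_prob = free_text_note_prob,
    free_text_start_year = as.integer(free_text_start_year),
    background_admission_rate = background_admission_rate,
    exclusion_condition_rate = exclusion_condition_rate
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  chk_prob <- function(x, field) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
      stop_config("invalid probability in field '%s'", field)
    }
  }
  chk_pos <- function(x, field) {
    if (any(!is.finite(unlist(x))) || any(unlist(x) <= 0)) {
      stop_config("field '%s' must be positive and finite", field)
    }
  }
  if (cfg$n_patients < 1L) stop_config("field 'n_patients' must be >= 1")
  if (cfg$n_practices < 1L) stop_config("field 'n_practices' must be >= 1")
  if (cfg$horizon_years <= 0) stop_config("field 'horizon_years' must be > 0")
  chk_prob(cfg$psych_prevalence, "psych_prevalence")
  chk_prob(cfg$treatment_given_psych, "treatment_given_psych")
  chk_prob(cfg$typical_fraction, "typical_fraction")
  chk_prob(cfg$prevalent_fraction, "prevalent_fraction")
  chk_prob(cfg$missing_rates, "missing_rates")
  chk_prob(cfg$hospitalised_death_fraction, "hospitalised_death_fraction")
  chk_prob(cfg$free_text_note_prob, "free_text_note_prob")
  chk_prob(cfg$scd_read_code_prob, "scd_read_code_prob")
  chk_prob(cfg$cardiac_read_code_prob, "cardiac_read_code_prob")
  chk_pos(cfg$true_rr, "true_rr")
  chk_pos(cfg$dose_rr, "dose_rr")
  bh <- unlist(cfg$baseline_hazards)
  if (any(!is.finite(bh)) || any(bh < 0)) {
    stop_config("field 'baseline_hazards' must be non-negative and finite")
  }
  ok_conf <- c("alcohol_drug_abuse", "diabetes", "suicide_attempt",
               "prior_psych_admission", "smoking_current")
  bad <- setdiff(names(cfg$confounder_effects), ok_conf)
  if (length(bad)) {
    stop_config("unknown covariate in field 'confounder_effects': %s",
                paste(bad, collapse = ", "))
  }
  invisible(cfg)
}

#' Read a simulation configuration from a YAML file
#'
#' The file holds any subset of [sim_config()]'s arguments under their
#' argument names; named vectors (prevalences, rates, dose multipliers)
#' are YAML mappings. Unknown keys are an error.
#'
#' @param path YAML file path.
#' @return a validated `sim_config`.
#' @export
sim_config_from_yaml <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) {
    stop_config("unknown configuration key(s): %s",
                paste(bad, collapse = ", "))
  }
  vec_fields <- c("psych_prevalence", "dose_band_probs", "rx_gap_profile",
                  "missing_rates", "dose_rr")
  for (f in intersect(vec_fields, names(y))) y[[f]] <- unlist(y[[f]])
  if ("confounder_effects" %in% names(y)) {
    y$confounder_effects <- lapply(y$confounder_effects, unlist)
  }
  do.call(sim_config, y)
}

# deterministic child seeds for the simulation stages, kept below 2^31
# (double arithmetic: the product can exceed the integer range)
stage_seed <- function(cfg, stage) {
  offs <- c(population = 11, prescribing = 23, outcomes = 37)
  as.integer((as.numeric(cfg$seed) * 1009 + offs[[stage]]) %% 2147483647)
}
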