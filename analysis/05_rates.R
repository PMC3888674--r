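#!/usr/bin/env Rscript
# Stage 5: person-time accumulation and Poisson rate-ratio estimation.
# Follow-up among users is restricted to current exposure. Three
# comparison sets are estimated for each outcome: current use vs matched
# general-population controls, current use vs psychiatric nonusers, and
# atypical vs typical (by first prescribed class, among users); each with
# an age/sex-adjusted and a fully adjusted model (backward elimination
# under the five-events-per-parameter budget, retention at P < 0.05,
# removal at P >= 0.10, missing-indicator levels for BMI and smoking).
# Dose-band and age-band stratified estimates and a cause-of-death chapter
# table are also written.

library(apcohort)
library(data.table)
setDTthreads(1L)

ehr <- read_ehr("results/ehr")
subjects <- fread("results/cohorts.csv")
timelines <- fread("results/exposure.csv")
adj <- fread("results/outcomes.csv")

spec <- model_spec()
sf <- subject_frame(subjects, ehr$patients, ehr$origin_date)
covars <- intersect(spec$candidates, names(sf))

comparisons <- list(
  user_vs_general = list(cohorts = c("user", "general_control"),
                         ref = "general_population"),
  user_vs_psych = list(cohorts = c("user", "psych_nonuser"),
                       ref = "psych_nonuser"))

estimates <- list()
cells_store <- list()
for (cmp in names(comparisons)) {
  cd <- comparisons[[cmp]]
  su <- sf[cohort %in% cd$cohorts]
  su[, exposure := fifelse(cohort == "user", "current_use", cd$ref)]
  for (oc in c("all_cause_mortality", "cardiac_mortality", "scd_primary",
               "scd_secondary", "scd_tertiary", "chd",
               "ventricular_arrhythmia")) {
    cells <- accumulate_person_time(su, timelines, adj, oc,
                                    covariates = covars,
                                    carry_cols = c("dose_band",
                                                   "cum_duration_band"))
    cells_store[[paste(cmp, oc)]] <- cells
    for (ad in c("age_sex", "full")) {
      est <- fit_rate_ratio(cells, reference = cd$ref, adjustment = ad,
                            spec = spec)
      est[, `:=`(comparison_set = cmp, outcome = oc)]
      estimates[[paste(cmp, oc, ad)]] <- est
    }
  }
}

# atypical vs typical among users, by first prescribed class
su <- sf[cohort == "user"]
su[, exposure := first_class]
for (oc in c("all_cause_mortality", "cardiac_mortality", "scd_secondary")) {
  cells <- accumulate_person_time(su, timelines, adj, oc,
                                  covariates = covars)
  for (ad in c("age_sex", "full")) {
    est <- fit_rate_ratio(cells, reference = "typical", adjustment = ad,
                          spec = spec)
    est[, `:=`(comparison_set = "atypical_vs_typical", outcome = oc)]
    estimates[[paste("avt", oc, ad)]] <- est
  }
}
estimates <- rbindlist(estimates, use.names = TRUE)
fwrite(estimates, "results/estimates.csv")

# stratified views of the psychiatric-nonuser comparison
strata <- list()
for (oc in c("all_cause_mortality", "cardiac_mortality", "scd_primary")) {
  cells <- cells_store[[paste("user_vs_psych", oc)]]
  dose <- stratified_rr(cells, by = "dose_band",
                        reference = "psych_nonuser")
  dose[, `:=`(stratifier = "dose_band", outcome = oc)]
  # coarse age groups for the stratified view
  su <- sf[cohort %in% c("user", "psych_nonuser")]
  su[, exposure := fifelse(cohort == "user", "current_use",
                           "psych_nonuser")]
  coarse <- accumulate_person_time(su, timelines, adj, oc,
                                   age_bands = c(30, 65, 80))
  age <- stratified_rr(coarse, by = "age_band",
                       reference = "psych_nonuser",
                       shared_reference = FALSE)
  age[, `:=`(stratifier = "age_band", outcome = oc)]
  strata[[oc]] <- rbind(dose, age)
}
fwrite(rbindlist(strata), "results/rates_by_stratum.csv")

# causes of death among current users by first prescribed class
cod <- cause_of_death_table(subjects[cohort == "user"], timelines,
                            ehr$events, ehr$patients)
fwrite(cod, "results/causes_of_death.csv")

show <- estimates[comparison_set == "user_vs_psych" &
                    adjustment == "full" & !nc,
                  .(outcome, rr = round(rr, 2), ci_low = round(ci_low, 2),
                    ci_high = round(ci_high, 2), events_exposed)]
cat("fully adjusted rate ratios, current use vs psychiatric nonusers:\n")
print(show)
cat("tables written: estimates.csv, rates_by_stratum.csv,",
    "causes_of_death.csv\n")
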