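test_that("identical configurations reproduce byte-identical tables", {
  a <- simulate_ehr(sim_config(n_patients = 2000, seed = 5))
  b <- simulate_ehr(sim_config(n_patients = 2000, seed = 5))
  for (nm in c("patients", "prescriptions", "events", "freetext")) {
    expect_identical(a[[nm]], b[[nm]])
  }
  c2 <- simulate_ehr(sim_config(n_patients = 2000, seed = 6))
  expect_false(identical(a$events, c2$events))
})

test_that("degenerate configurations behave as configured", {
  zero_psych <- sim_config(n_patients = 1500, seed = 3,
                           psych_prevalence = c(schizophrenia = 0,
                                                bipolar = 0,
                                                major_depression = 0,
                                                dementia = 0))
  sim <- simulate_ehr(zero_psych)
  expect_false(any(sim$patients$.psych))
  expect_equal(nrow(sim$prescriptions), 0L)

  all_typical <- simulate_ehr(sim_config(n_patients = 4000, seed = 3,
                                         typical_fraction = 1))
  expect_true(all(all_typical$prescriptions$drug_class == "typical"))

  # heavy strength missingness: every affected dose is flagged as imputed;
  # with no calculable dose anywhere imputation is impossible and says so
  mostly_missing <- simulate_ehr(sim_config(
    n_patients = 4000, seed = 3,
    missing_rates = c(bmi = 0.2, smoking = 0.15, quantity = 0.02,
                      prescribed_daily_dose = 0.02, strength = 0.9)))
  ep <- compute_ddd(mostly_missing$prescriptions)
  expect_true(all(ep[is.na(strength), ddd_imputed]))
  all_missing <- data.table::copy(mostly_missing$prescriptions)
  all_missing[, strength := NA_real_]
  expect_error(compute_ddd(all_missing), "no calculable")
})

test_that("zero baseline hazards produce no outcome events", {
  cfg <- sim_config(n_patients = 1500, seed = 4,
                    baseline_hazards = list(scd = 0, cardiac_other = 0,
                                            other_mortality = 0,
                                            suicide = 0, chd = 0,
                                            ventricular_arrhythmia = 0))
  sim <- simulate_ehr(cfg)
  expect_false(any(!is.na(sim$patients$death_date)))
  expect_equal(nrow(sim$events[source == "death_certificate"]), 0L)
})

test_that("gaps always inside the grace window yield a single treatment
           episode per user", {
  # fully observed prescription fields: with missingness, an imputed
  # (shortened) duration can legitimately split a chain
  cfg <- sim_config(n_patients = 4000, seed = 8,
                    rx_gap_profile = c(continuous = 1, recent_break = 0,
                                       long_break = 0),
                    prevalent_fraction = 0,
                    missing_rates = c(bmi = 0.2, smoking = 0.15,
                                      quantity = 0,
                                      prescribed_daily_dose = 0,
                                      strength = 0))
  sim <- simulate_ehr(cfg)
  users <- identify_users(sim$patients, sim$prescriptions)
  tl <- build_timelines(prepare_episodes(sim$prescriptions),
                        users[, .(patient_id, censor_date)])
  # one contiguous run of current intervals per patient
  runs <- tl[, {
    cur <- state == "current"
    .(n_runs = sum(cur & !c(FALSE, cur[-length(cur)])))
  }, by = patient_id]
  expect_true(all(runs$n_runs == 1L))
})

test_that("a simulation configuration round-trips through YAML", {
  y <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_patients: 500", "seed: 3", "typical_fraction: 0.7",
               "psych_prevalence:", "  schizophrenia: 0.05",
               "  bipolar: 0.0", "  major_depression: 0.1",
               "  dementia: 0.0"), y)
  cfg <- sim_config_from_yaml(y)
  expect_equal(cfg$n_patients, 500L)
  expect_equal(cfg$typical_fraction, 0.7)
  expect_equal(unname(cfg$psych_prevalence["schizophrenia"]), 0.05)
  expect_identical(simulate_ehr(cfg)$patients,
                   simulate_ehr(sim_config(
                     n_patients = 500, seed = 3, typical_fraction = 0.7,
                     psych_prevalence = c(schizophrenia = 0.05, bipolar = 0,
                                          major_depression = 0.1,
                                          dementia = 0)))$patients)
  writeLines("not_a_key: 1", y)
  expect_error(sim_config_from_yaml(y), "unknown configuration key")
})

test_that("invalid configuration values name the offending field", {
  expect_error(sim_config(treatment_given_psych = 1.2),
               "treatment_given_psych")
  expect_error(sim_config(baseline_hazards = list(scd = -1)),
               "baseline_hazards")
  expect_error(sim_config(confounder_effects = list(nope = c(treat = 1,
                                                             outcome = 1))),
               "confounder_effects")
})

test_that("treatment assignment hits the configured probability", {
  cfg <- sim_config(n_patients = 50000, seed = 11,
                    treatment_given_psych = 0.5)
  pts <- generate_population(cfg)
  rx <- generate_prescribing(pts, cfg)
  psych <- pts[.psych == TRUE]
  frac <- mean(psych$patient_id %in% rx$patient_id)
  n <- nrow(psych)
  mc_se <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(frac - 0.5), 3 * mc_se)
})

test_that("record streams satisfy their structural invariants", {
  sim <- cached_sim()
  v <- validate_inputs(sim)
  # historical exclusion-condition codes legitimately predate registration
  # (transferred records); everything else must be clean
  expect_true(all(v[check != "event_before_registration", n_violations] == 0))
  pre_reg <- merge(sim$events,
                   sim$patients[, .(patient_id, registration_date)],
                   by = "patient_id")[date < registration_date]
  expect_equal(v[check == "event_before_registration", n_violations],
               nrow(pre_reg))
  expect_true(all(pre_reg$code %in%
                    load_code_sets()$exclusion_conditions$pre_index))
  # notes only near deaths
  ft <- merge(sim$freetext, sim$patients[, .(patient_id, death_date)],
              by = "patient_id")
  expect_true(all(abs(ft$date - ft$death_date) <= 21))
  # at most one first-record date per disease is structural (one column
  # each); hospital rows carry ordered episode dates
  hosp <- sim$events[source == "hospital"]
  expect_true(all(hosp$admission_date <= hosp$discharge_date))
})

test_that("event counts match the closed-form constant-hazard expectation", {
  # no treatment, no covariate effects: every death cause is a constant
  # hazard, so E[events] = person-years x rate
  cfg <- sim_config(n_patients = 50000, seed = 21,
                    psych_prevalence = c(schizophrenia = 0, bipolar = 0,
                                         major_depression = 0, dementia = 0),
                    age_log_hr_per_decade = 0, male_log_hr = 0,
                    psych_log_hr = 0)
  sim <- simulate_ehr(cfg)
  p <- sim$patients
  py <- sum(p$.end_fu - p$.entry) / 365.25
  h_death <- with(cfg$baseline_hazards,
                  scd + cardiac_other + other_mortality + suicide)
  n_death <- p[!is.na(death_date), .N]
  # deaths are right-censored draws from rate h_death over ~py at-risk years
  expect_lt(abs(n_death - py * h_death), 4 * sqrt(py * h_death))
})

test_that("written tables round-trip through the delimited files", {
  sim <- simulate_ehr(sim_config(n_patients = 800, seed = 9))
  dir <- withr::local_tempdir()
  write_ehr(sim, dir)
  expect_true(all(file.exists(file.path(dir, c("patients.csv",
                                               "prescriptions.csv",
                                               "events.csv", "freetext.csv",
                                               "manifest.json")))))
  back <- read_ehr(dir)
  expect_equal(nrow(back$patients), nrow(sim$patients))
  expect_equal(back$prescriptions$date, sim$prescriptions$date)
  expect_false(any(grepl("^\\.true", names(back$prescriptions))))
  expect_equal(back$patients$death_date, sim$patients$death_date)
})
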