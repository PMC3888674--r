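ALL_OUTCOMES <- c("all_cause_mortality", "cardiac_mortality", "scd_primary",
                  "scd_secondary", "scd_tertiary", "chd",
                  "ventricular_arrhythmia")

#' Validate the four input tables
#'
#' Schema, date-ordering and referential-integrity checks with
#' per-violation counts: unknown patient ids in the linked tables, events
#' dated before registration, hospital rows with admission after discharge,
#' death-certificate rows not dated at the patient's death date, and notes
#' outside the three-week window around death.
#'
#' @param data list with `patients`, `prescriptions`, `events`, `freetext`.
#' @return `data.table` of checks and violation counts.
#' @export
validate_inputs <- function(data) {
  p <- data$patients
  need <- c("patient_id", "practice_id", "sex", "birth_year",
            "registration_date", "data_start")
  miss <- setdiff(need, names(p))
  if (length(miss)) {
    stop_config("patients table lacks column(s): %s",
                paste(miss, collapse = ", "))
  }
  ids <- p$patient_id
  reg <- p[, .(patient_id, registration_date, death_date)]
  ev <- merge(data$events, reg, by = "patient_id", all.x = TRUE)
  nt <- merge(data$freetext, reg, by = "patient_id", all.x = TRUE)
  checks <- data.table::data.table(
    check = c("prescription_for_unknown_patient",
              "event_for_unknown_patient",
              "note_for_unknown_patient",
              "event_before_registration",
              "hospital_admission_after_discharge",
              "death_certificate_not_on_death_date",
              "note_outside_death_window"),
    n_violations = c(
      sum(!data$prescriptions$patient_id %in% ids),
      sum(!data$events$patient_id %in% ids),
      sum(!data$freetext$patient_id %in% ids),
      ev[, sum(date < registration_date, na.rm = TRUE)],
      data$events[source == "hospital",
                  sum(admission_date > discharge_date, na.rm = TRUE)],
      ev[source == "death_certificate",
         sum(is.na(death_date) | date != death_date)],
      nt[, sum(is.na(death_date) |
                 abs(date - death_date) > FREE_TEXT_WINDOW_DAYS)]))
  checks
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> cohort construction -> exclusions ->
#' exposure standardisation and timelines -> free-text search and outcome
#' adjudication -> person-time accumulation and Poisson rate-ratio
#' estimation, optionally followed by smoothed hazard-ratio curves over
#' treatment time. Deterministic given the configuration (including its
#' seed).
#'
#' @param config a [sim_config()] (data are generated) or a directory
#'   written by [write_ehr()] (data are loaded).
#' @param comparisons any of `"user_vs_psych"` (current use vs psychiatric
#'   nonusers), `"user_vs_general"` (current use vs matched controls) and
#'   `"atypical_vs_typical"` (by first prescribed class, among users).
#' @param outcomes outcomes to estimate.
#' @param adjustments any of `"crude"`, `"age_sex"`, `"full"`.
#' @param criteria a [match_criteria()] for control matching.
#' @param spec a [model_spec()] for full adjustment.
#' @param smooth build smoothed all-cause hazard curves by first class and
#'   their ratio (atypical vs typical).
#' @param n_periods,bandwidth_periods smoothing grid settings.
#' @param use_free_text run the free-text search (practice-volume and
#'   start-year restrictions apply).
#' @return list with the cohort table, timelines, adjudicated outcomes,
#'   estimates, per-comparison cells, optional curves, and a run manifest.
#' @export
run_pipeline <- function(config = sim_config(),
                         comparisons = c("user_vs_psych", "user_vs_general",
                                         "atypical_vs_typical"),
                         outcomes = ALL_OUTCOMES,
                         adjustments = c("age_sex", "full"),
                         criteria = match_criteria(),
                         spec = model_spec(),
                         smooth = FALSE, n_periods = 100L,
                         bandwidth_periods = 5,
                         use_free_text = TRUE) {
  if (is.character(config)) {
    data <- read_ehr(config)
    origin <- data$origin_date
    seed <- 1L
  } else {
    data <- simulate_ehr(config)
    origin <- config$origin_date
    seed <- config$seed
  }
  code_sets <- load_code_sets()

  users <- identify_users(data$patients, data$prescriptions)
  nonusers <- identify_psych_nonusers(data$patients, data$prescriptions)
  subjects <- rbind(users, nonusers)
  if ("user_vs_general" %in% comparisons) {
    controls <- match_controls(users, data$patients, data$prescriptions,
                               criteria, seed = seed)
    subjects <- rbind(subjects, controls)
  }
  subjects <- apply_exclusions(subjects, data$events, data$patients,
                               code_sets)
  flow <- attr(subjects, "exclusion_flow")

  episodes <- prepare_episodes(data$prescriptions)
  u_censor <- subjects[cohort == "user", .(patient_id, censor_date)]
  timelines <- build_timelines(episodes, u_censor)

  ft <- if (use_free_text) {
    start_year <- if (is.character(config)) NULL else
      config$free_text_start_year
    search_free_text(data$freetext, data$patients, code_sets,
                     start_year = start_year, origin_date = origin)
  } else {
    search_free_text(data$freetext[0], data$patients, code_sets)
  }
  adj <- adjudicate_outcomes(subjects, data$events, ft, data$patients,
                             code_sets)

  sf <- subject_frame(subjects, data$patients, origin)
  covars <- intersect(spec$candidates, names(sf))

  comp_def <- list(
    user_vs_psych = list(
      cohorts = c("user", "psych_nonuser"),
      label = function(s) data.table::fifelse(s$cohort == "user",
                                              "current_use",
                                              "psych_nonuser"),
      reference = "psych_nonuser"),
    user_vs_general = list(
      cohorts = c("user", "general_control"),
      label = function(s) data.table::fifelse(s$cohort == "user",
                                              "current_use",
                                              "general_population"),
      reference = "general_population"),
    atypical_vs_typical = list(
      cohorts = "user",
      label = function(s) s$first_class,
      reference = "typical"))

  estimates <- list()
  cells_out <- list()
  for (cmp in comparisons) {
    cd <- comp_def[[cmp]]
    su <- sf[cohort %in% cd$cohorts]
    su[, exposure := cd$label(su)]
    for (oc in outcomes) {
      cells <- accumulate_person_time(
        su, timelines, adj, oc, covariates = covars,
        carry_cols = c("dose_band", "cum_duration_band", "drug_class"))
      cells_out[[paste(cmp, oc, sep = ".")]] <- cells
      for (ad in adjustments) {
        est <- fit_rate_ratio(cells, reference = cd$reference,
                              adjustment = ad, spec = spec)
        est[, `:=`(comparison_set = cmp, outcome = oc)]
        estimates[[paste(cmp, oc, ad, sep = ".")]] <- est
      }
    }
  }
  estimates <- data.table::rbindlist(estimates, use.names = TRUE)

  curves <- NULL
  if (smooth) {
    curves <- treatment_time_curves(sf, adj, "all_cause_mortality",
                                    n_periods, bandwidth_periods)
  }

  manifest <- list(
    seed = seed,
    origin_date = format(origin),
    config_hash = config_hash(config),
    n_subjects = as.list(table(subjects$cohort)),
    n_prescriptions = nrow(data$prescriptions),
    n_events = nrow(data$events),
    n_notes = nrow(data$freetext),
    exclusion_flow = flow)

  list(data = data, subjects = subjects, timelines = timelines,
       episodes = episodes, free_text_matches = ft, outcomes = adj,
       cells = cells_out, estimates = estimates, curves = curves,
       imputation = imputation_summary(episodes), manifest = manifest)
}

# smoothed hazard curves over time since treatment start, by first
# prescribed class, plus their ratio (atypical / typical)
treatment_time_curves <- function(sf, adj, outcome_name, n_periods,
                                  bandwidth_periods) {
  users <- sf[cohort == "user"]
  ev <- adj[outcome == outcome_name & cohort == "user",
            .(event_date = min(event_date)), by = patient_id]
  users <- merge(users, ev, by = "patient_id", all.x = TRUE)
  users[, fu := (pmin(censor_date, event_date, na.rm = TRUE) -
                   index_date) / DAYS_PER_YEAR]
  users[, et := (event_date - index_date) / DAYS_PER_YEAR]
  users <- users[fu > 0]
  t_max <- max(users$fu)
  grids <- lapply(split(users, users$first_class), function(g) {
    build_hazard_grid(g$fu, g$et, n_periods = n_periods, t_max = t_max)
  })
  bw <- bandwidth_periods * t_max / n_periods
  curves <- lapply(grids, smooth_hazard, bandwidth = bw)
  ratio <- if (all(c("atypical", "typical") %in% names(curves))) {
    hazard_ratio_curve(curves$atypical, curves$typical)
  }
  list(grids = grids, curves = curves, ratio = ratio)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  obj <- if (is.character(config)) list(input_dir = config) else
    lapply(unclass(config), function(x) {
      if (inherits(x, "Date")) format(x) else x
    })
  yaml::write_yaml(obj, f)
  unname(tools::md5sum(f))
}

#' Write pipeline outputs as delimited files
#'
#' Emits `cohorts.csv`, `exposure.csv`, `outcomes.csv`, `estimates.csv`,
#' `imputation_summary.csv`, `exclusion_flow.csv`, optional curve files,
#' and `manifest.json` into `dir`.
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(result$subjects, file.path(dir, "cohorts.csv"))
  data.table::fwrite(result$timelines, file.path(dir, "exposure.csv"))
  data.table::fwrite(result$outcomes, file.path(dir, "outcomes.csv"))
  data.table::fwrite(result$estimates, file.path(dir, "estimates.csv"))
  data.table::fwrite(result$imputation,
                     file.path(dir, "imputation_summary.csv"))
  data.table::fwrite(result$manifest$exclusion_flow,
                     file.path(dir, "exclusion_flow.csv"))
  if (!is.null(result$curves)) {
    for (nm in names(result$curves$curves)) {
      data.table::fwrite(result$curves$curves[[nm]],
                         file.path(dir, paste0("hazard_curve_", nm, ".csv")))
    }
    if (!is.null(result$curves$ratio)) {
      data.table::fwrite(result$curves$ratio,
                         file.path(dir, "hazard_ratio_curve.csv"))
    }
  }
  man <- result$manifest
  man$exclusion_flow <- NULL
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
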