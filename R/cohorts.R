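#' Identify antipsychotic users and their index dates
#'
#' One subject per patient with at least one antipsychotic prescription
#' inside their observed period. The index date is the first prescription on
#' or after the start of the patient's data collection; users with an
#' earlier (pre-collection) prescription are prevalent, the rest incident.
#' `first_class` is the drug class prescribed at the index date (ties on the
#' same day resolved by alphabetical drug name).
#'
#' @param patients patients table (with `.entry`/`.end_fu` bookkeeping, as
#'   produced by the generator or [read_ehr()]).
#' @param prescriptions prescriptions table.
#' @return `data.table` of indexed subjects (cohort `"user"`).
#' @export
identify_users <- function(patients, prescriptions) {
  rx <- check_rx_linkage(patients, prescriptions)
  drugs <- antipsychotic_drugs()
  rx <- rx[drug_name %in% drugs$drug_name]
  rx <- merge(rx, patients[, .(patient_id, .entry, .end_fu)],
              by = "patient_id")
  instudy <- rx[date >= .entry]
  if (nrow(instudy) == 0L) return(empty_subjects())
  data.table::setorder(instudy, patient_id, date, drug_name)
  idx <- instudy[, .(index_date = date[1L],
                     first_class = drug_class[1L]), by = patient_id]
  pre <- rx[date < .entry, .(has_pre = .N > 0L), by = patient_id]
  idx <- merge(idx, pre, by = "patient_id", all.x = TRUE)
  idx[, user_type := data.table::fifelse(is.na(has_pre), "incident",
                                         "prevalent")]
  out <- merge(idx, patients[, .(patient_id, .end_fu)], by = "patient_id")
  out[, `:=`(cohort = "user", censor_date = .end_fu,
             match_group = NA_integer_, has_pre = NULL, .end_fu = NULL)]
  out <- out[censor_date > index_date]
  data.table::setcolorder(out, c("patient_id", "cohort", "index_date",
                                 "user_type", "first_class", "censor_date",
                                 "match_group"))
  out[]
}

#' Matching criteria for general-population controls
#'
#' @param age_tolerance maximum birth-year difference in years.
#' @param calendar_tolerance allowed difference between user and control
#'   index dates in days (0 = controls inherit the user's index date).
#' @param ratio controls per user.
#' @export
match_criteria <- function(age_tolerance = 2, calendar_tolerance = 0,
                           ratio = 3L) {
  stopifnot(ratio >= 1L, age_tolerance >= 0, calendar_tolerance >= 0)
  list(age_tolerance = age_tolerance,
       calendar_tolerance = calendar_tolerance, ratio = as.integer(ratio))
}

#' Match general-population controls to users
#'
#' Up to `ratio` controls per user, matched on sex and practice with birth
#' year within `age_tolerance`; the control inherits the user's index date,
#' which must fall at least 12 months after the start of the control's data
#' collection and inside the control's registered period. Eligible controls
#' have no psychiatric diagnosis ever recorded and no antipsychotic
#' prescription on or before the index date; a control prescribed
#' antipsychotics later is censored at that first prescription. Sampling
#' within a match group is without replacement with a seeded tie-break;
#' users with fewer than `ratio` eligible candidates keep what exists and
#' are flagged (`n_controls`).
#'
#' @param users output of [identify_users()].
#' @param patients patients table.
#' @param prescriptions prescriptions table.
#' @param criteria a [match_criteria()].
#' @param seed integer seed for the sampling tie-break.
#' @return `data.table` of control subjects (cohort `"general_control"`);
#'   the per-user control count is attached as attribute `"match_summary"`.
#' @export
match_controls <- function(users, patients, prescriptions,
                           criteria = match_criteria(), seed = 1L) {
  set.seed(seed %% 2147483647L)
  pool <- patients[is.na(dx_schizophrenia) & is.na(dx_bipolar) &
                     is.na(dx_major_depression) & is.na(dx_dementia)]
  first_rx <- prescriptions[, .(first_rx = min(date)), by = patient_id]
  pool <- merge(pool, first_rx, by = "patient_id", all.x = TRUE)

  u <- merge(users, patients[, .(patient_id, practice_id, sex, birth_year)],
             by = "patient_id")
  cand <- pool[, .(ctrl_id = patient_id, practice_id, sex, birth_year,
                   c_entry = .entry, c_end = .end_fu, first_rx)]
  joined <- cand[u, on = .(practice_id, sex), allow.cartesian = TRUE,
                 nomatch = NULL]
  # i-columns: patient_id (user), index_date, birth_year is masked -> use i.
  joined <- joined[abs(birth_year - i.birth_year) <= criteria$age_tolerance &
                     ctrl_id != patient_id &
                     index_date >= c_entry + 12 * DAYS_PER_MONTH &
                     index_date < c_end &
                     (is.na(first_rx) | first_rx > index_date)]
  if (nrow(joined) == 0L) {
    out <- empty_subjects()
    attr(out, "match_summary") <- data.table::data.table(
      patient_id = users$patient_id, n_controls = 0L)
    return(out)
  }
  # seeded tie-break: random rank within user, keep the first `ratio`
  joined[, rnd := runif(.N)]
  data.table::setorder(joined, patient_id, rnd)
  picked <- joined[, utils::head(.SD, criteria$ratio), by = patient_id,
                   .SDcols = c("ctrl_id", "index_date", "c_end", "first_rx")]
  out <- picked[, .(
    patient_id = ctrl_id, cohort = "general_control",
    index_date,
    user_type = NA_character_, first_class = NA_character_,
    censor_date = pmin(c_end, first_rx, na.rm = TRUE),
    # match_group identifies the user each control belongs to
    match_group = patient_id)]
  out <- out[censor_date > index_date]
  summary <- out[, .(n_controls = .N), by = match_group]
  summary <- merge(data.table::data.table(patient_id = users$patient_id),
                   summary, by.x = "patient_id", by.y = "match_group",
                   all.x = TRUE)
  summary[is.na(n_controls), n_controls := 0L]
  attr(out, "match_summary") <- summary
  out[]
}

#' Identify the psychiatric nonuser cohort
#'
#' One subject per patient with a recorded psychiatric diagnosis and no
#' antipsychotic prescription before the first diagnosis record; the index
#' date is that first record and follow-up is additionally censored at the
#' first antipsychotic prescription. This cohort is unmatched.
#'
#' @inheritParams identify_users
#' @return `data.table` of subjects (cohort `"psych_nonuser"`).
#' @export
identify_psych_nonusers <- function(patients, prescriptions) {
  check_rx_linkage(patients, prescriptions)
  p <- patients[!is.na(dx_schizophrenia) | !is.na(dx_bipolar) |
                  !is.na(dx_major_depression) | !is.na(dx_dementia)]
  if (nrow(p) == 0L) return(empty_subjects())
  p[, first_dx := pmin(dx_schizophrenia, dx_bipolar, dx_major_depression,
                       dx_dementia, na.rm = TRUE)]
  first_rx <- prescriptions[, .(first_rx = min(date)), by = patient_id]
  p <- merge(p, first_rx, by = "patient_id", all.x = TRUE)
  p <- p[is.na(first_rx) | first_rx >= first_dx]
  out <- p[, .(patient_id, cohort = "psych_nonuser", index_date = first_dx,
               user_type = NA_character_, first_class = NA_character_,
               censor_date = pmin(.end_fu, first_rx, na.rm = TRUE),
               match_group = NA_integer_)]
  out[censor_date > index_date]
}

#' Apply cardiac exclusion rules
#'
#' Removes subjects with a congenital conduction disorder or advanced
#' cardiomyopathy code at any time in the record, and subjects with a
#' life-threatening ventricular tachyarrhythmia, cardioversion, aborted
#' cardiac arrest or defibrillator-implantation code on or before their
#' registration date or on or before their index date. Controls orphaned by
#' the exclusion of their user are removed too. Per-rule counts are
#' attached as attribute `"exclusion_flow"`.
#'
#' @param subjects stacked cohort table.
#' @param events coded events table.
#' @param patients patients table (registration dates).
#' @param code_sets packaged code sets from [load_code_sets()].
#' @return filtered subjects with an exclusion-flow attribute.
#' @export
apply_exclusions <- function(subjects, events, patients,
                             code_sets = load_code_sets()) {
  ex <- code_sets$exclusion_conditions
  subj <- data.table::copy(subjects)
  subj[, row_id := .I]
  ev <- events[code %in% c(ex$any_time, ex$pre_index)]
  ev <- merge(ev, patients[, .(patient_id, registration_date)],
              by = "patient_id")

  any_ids <- unique(ev[code %in% ex$any_time, patient_id])
  pre_reg_ids <- unique(ev[code %in% ex$pre_index &
                             date <= registration_date, patient_id])
  vt <- ev[code %in% ex$pre_index]
  pre_idx <- unique(
    vt[subj, on = .(patient_id, date <= index_date), nomatch = NULL,
       .(patient_id = i.patient_id)])$patient_id

  flow <- data.table::data.table(
    rule = c("congenital_conduction_or_cardiomyopathy_any_time",
             "tachyarrhythmia_set_on_or_before_registration",
             "tachyarrhythmia_set_on_or_before_index"),
    n_subjects = c(sum(subj$patient_id %in% any_ids),
                   sum(subj$patient_id %in% pre_reg_ids),
                   sum(subj$patient_id %in% pre_idx)))

  drop_ids <- unique(c(any_ids, pre_reg_ids, pre_idx))
  kept <- subj[!patient_id %in% drop_ids]
  # remove controls whose matched user was excluded
  excluded_users <- subj[cohort == "user" & patient_id %in% drop_ids,
                         patient_id]
  orphan <- kept[cohort == "general_control" &
                   match_group %in% excluded_users, row_id]
  flow <- rbind(flow, data.table::data.table(
    rule = "orphaned_controls_of_excluded_users",
    n_subjects = length(orphan)))
  kept <- kept[!row_id %in% orphan]
  kept[, row_id := NULL]
  attr(kept, "exclusion_flow") <- flow
  kept[]
}

empty_subjects <- function() {
  data.table::data.table(
    patient_id = integer(), cohort = character(), index_date = numeric(),
    user_type = character(), first_class = character(),
    censor_date = numeric(), match_group = integer())
}

check_rx_linkage <- function(patients, prescriptions) {
  bad <- setdiff(prescriptions$patient_id, patients$patient_id)
  if (length(bad)) {
    stop_config("prescriptions reference %d unknown patient id(s), e.g. %s",
                length(bad), bad[1])
  }
  prescriptions
}
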