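#' Attach analysis covariates to cohort subjects
#'
#' Joins patient-level covariates to subjects and derives the modelling
#' variables: mid-year birth day offset, body-mass-index band and smoking
#' status with explicit `missing` levels (the missing-indicator method),
#' and character versions of the binary flags.
#'
#' @param subjects stacked cohort table.
#' @param patients patients table.
#' @param origin_date origin used when the tables were generated.
#' @return subjects with covariate columns added.
#' @export
subject_frame <- function(subjects, patients,
                          origin_date = as.Date("2000-01-01")) {
  origin_year <- as.integer(format(as.Date(origin_date), "%Y"))
  cols <- c("patient_id", "sex", "birth_year", "smoking", "bmi",
            "alcohol_drug_abuse", "diabetes", "suicide_attempt",
            "deprivation", "prior_psych_admission", "antidepressant",
            "anxiolytic")
  out <- merge(subjects, patients[, .SD, .SDcols = cols],
               by = "patient_id")
  out[, birth_day := (birth_year - origin_year) * DAYS_PER_YEAR]
  out[, smoking := data.table::fifelse(is.na(smoking), "missing", smoking)]
  out[, bmi_band := data.table::fcase(
    is.na(bmi), "missing",
    bmi < 18.5, "under",
    bmi < 25, "normal",
    bmi < 30, "over",
    default = "obese")]
  out[, deprivation := as.character(deprivation)]
  out[]
}

#' Accumulate person-time into stratified cells
#'
#' Splits each subject's follow-up at every stratum boundary — current-
#' exposure changes (for subjects analysed on current exposure only),
#' age-band birthdays and dose/duration band changes — and assigns the
#' outcome event to the cell active at the event date. Follow-up for a
#' given outcome ends at the earlier of the censor date and the first
#' event. For subjects in the `user` cohort, person-time is restricted to
#' current-exposure segments when `user_time = "current"`.
#'
#' @param subjects output of [subject_frame()] with an `exposure` column
#'   labelling the comparison group of each subject.
#' @param timelines exposure intervals from [build_timelines()] (users).
#' @param outcomes adjudicated outcomes ([adjudicate_outcomes()]).
#' @param outcome_name outcome to analyse.
#' @param age_bands age band edges in years (default: ten-year bands,
#'   matching the simulator's attained-age hazard steps; coarser bands,
#'   e.g. `c(30, 65, 80)`, suit stratified reporting).
#' @param covariates subject-level covariate columns to keep in the cells.
#' @param carry_cols timeline columns carried into user cells
#'   (`dose_band`, `cum_duration_band`, `drug_class`).
#' @param user_time `"current"` (default) restricts user person-time to
#'   current exposure; `"all"` uses the whole follow-up.
#' @return `data.table` of cells with `events`, `person_years` and
#'   `rate_per_1000py`.
#' @export
accumulate_person_time <- function(subjects, timelines, outcomes,
                                   outcome_name,
                                   age_bands = AGE_BAND_EDGES,
                                   covariates = character(),
                                   carry_cols = character(),
                                   user_time = c("current", "all")) {
  user_time <- match.arg(user_time)
  stopifnot("exposure" %in% names(subjects))
  ev <- outcomes[outcome == outcome_name,
                 .(patient_id, cohort, event_date)]
  if (nrow(ev)) {
    ev <- ev[, .(event_date = min(event_date)), by = .(patient_id, cohort)]
  }
  su <- merge(subjects, ev, by = c("patient_id", "cohort"), all.x = TRUE)
  su[, end := pmin(censor_date, event_date, na.rm = TRUE)]
  su <- su[end > index_date]
  su[, sub_id := .I]

  keep <- c("sub_id", "patient_id", "exposure", "sex", "birth_day",
            "index_date", "end", "event_date", covariates)

  is_user <- su$cohort == "user"
  segs_list <- list()
  if (user_time == "current" && any(is_user)) {
    uu <- su[is_user == TRUE, ..keep]
    cur <- timelines[state == "current"]
    j <- cur[uu, on = "patient_id", nomatch = NULL, allow.cartesian = TRUE]
    j[, `:=`(s = pmax(start, index_date), e = pmin(end, i.end))]
    j <- j[e > s]
    seg_cols <- c("sub_id", "exposure", "sex", "birth_day", "event_date",
                  covariates, intersect(carry_cols, names(j)))
    segs_list$users <- j[, c(seg_cols, "s", "e"), with = FALSE]
    rest <- su[is_user == FALSE, ..keep]
  } else {
    rest <- su[, ..keep]
  }
  if (nrow(rest)) {
    rest[, `:=`(s = index_date, e = end)]
    for (cc in carry_cols) rest[, (cc) := NA_character_]
    seg_cols <- c("sub_id", "exposure", "sex", "birth_day", "event_date",
                  covariates, carry_cols)
    segs_list$rest <- rest[, c(seg_cols, "s", "e"), with = FALSE]
  }
  segs <- data.table::rbindlist(segs_list, use.names = TRUE, fill = TRUE)
  if (nrow(segs) == 0L) {
    stop_config("no person-time segments inside follow-up")
  }

  # split at age-band birthdays
  segs[, seg_id := .I]
  cr <- list()
  for (edge in age_bands) {
    cross <- segs$birth_day + edge * DAYS_PER_YEAR
    hit <- cross > segs$s & cross < segs$e
    if (any(hit)) {
      cr[[as.character(edge)]] <- data.table::data.table(
        seg_id = segs$seg_id[hit], t = cross[hit])
    }
  }
  cr <- data.table::rbindlist(cr)
  bp <- rbind(segs[, .(seg_id, t = s)], cr,
              segs[, .(seg_id, t = e)])
  data.table::setorder(bp, seg_id, t)
  bp <- unique(bp)
  bp[, e2 := data.table::shift(t, type = "lead"), by = seg_id]
  sub <- bp[!is.na(e2) & e2 > t]
  attr_cols <- setdiff(names(segs), c("s", "e"))
  sub <- merge(sub, segs[, ..attr_cols], by = "seg_id", sort = FALSE)

  sub[, age_band := age_band_label((t - birth_day) / DAYS_PER_YEAR,
                                   age_bands)]
  # the event belongs to the latest sub-segment starting on/before it and
  # not ending before it (so an event at the closing boundary is kept)
  sub[, event := FALSE]
  has_ev <- sub[!is.na(event_date) & t <= event_date & event_date <= e2]
  if (nrow(has_ev)) {
    data.table::setorder(has_ev, sub_id, t)
    last <- has_ev[, .(seg_pick = seg_id[.N], t_pick = t[.N]), by = sub_id]
    sub[last, on = .(sub_id, seg_id = seg_pick, t = t_pick), event := TRUE]
  }

  group_cols <- c("exposure", "age_band", "sex", covariates,
                  intersect(carry_cols, names(sub)))
  cells <- sub[, .(events = sum(event), person_years = sum(e2 - t) /
                     DAYS_PER_YEAR), by = group_cols]
  cells[, rate_per_1000py := 1000 * events / person_years]
  data.table::setorderv(cells, group_cols)
  cells[]
}

age_band_label <- function(age, bands = AGE_BAND_EDGES) {
  edges <- c(-Inf, bands, Inf)
  labels <- character(length(bands) + 1L)
  labels[1] <- sprintf("<%g", bands[1])
  if (length(bands) > 1L) {
    for (k in seq_len(length(bands) - 1L)) {
      labels[k + 1L] <- sprintf("%g-%g", bands[k], bands[k + 1L] - 1)
    }
  }
  labels[length(labels)] <- sprintf(">=%g", bands[length(bands)])
  labels[findInterval(age, c(bands, Inf)) + 1L]
}
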