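#' Practice-level free-text eligibility
#'
#' Free text is only usable in practices with an above-median amount of
#' free text per patient and from a configured start year onwards. The
#' volume statistic is total note characters divided by the number of
#' registered patients, per practice; the median is taken across all
#' practices in the population.
#'
#' @param notes free-text notes table (with `practice_id`).
#' @param patients patients table.
#' @return integer vector of eligible practice ids.
#' @export
free_text_eligibility <- function(notes, patients) {
  vol <- notes[, .(chars = sum(nchar(text))), by = practice_id]
  per <- patients[, .(n_pat = .N), by = practice_id]
  per <- merge(per, vol, by = "practice_id", all.x = TRUE)
  per[is.na(chars), chars := 0]
  per[, cpp := chars / n_pat]
  per[cpp > stats::median(cpp), practice_id]
}

#' Search free text around death dates for sudden-death trigger strings
#'
#' Case-insensitive substring search over notes dated within three weeks of
#' the patient's death, in eligible practices and from the configured start
#' year. A context window of at most 500 characters before and after the
#' matched string is extracted. The verdict is `scd` unless a configured
#' exclusion phrase (another clearly specified cause of death) appears in
#' the note.
#'
#' @param notes free-text notes table.
#' @param patients patients table (death dates, practice linkage).
#' @param code_sets packaged code sets ([load_code_sets()]).
#' @param eligible_practices from [free_text_eligibility()]; `NULL` computes
#'   it, `NA` disables the practice restriction.
#' @param start_year first calendar year of usable free text (`NULL`
#'   disables the restriction).
#' @param origin_date origin for converting day offsets to calendar years.
#' @return `data.table` of matches with `verdict` (`scd` / `not_scd`).
#' @export
search_free_text <- function(notes, patients, code_sets = load_code_sets(),
                             eligible_practices = NULL,
                             start_year = NULL,
                             origin_date = as.Date("2000-01-01")) {
  empty <- data.table::data.table(
    patient_id = integer(), date = numeric(), matched_string = character(),
    context = character(), verdict = character())
  if (nrow(notes) == 0L) return(empty)
  if (is.null(eligible_practices)) {
    eligible_practices <- free_text_eligibility(notes, patients)
  }
  nt <- merge(notes, patients[, .(patient_id, death_date)],
              by = "patient_id")
  nt <- nt[!is.na(death_date) &
             abs(date - death_date) <= FREE_TEXT_WINDOW_DAYS]
  if (length(eligible_practices) == 1L && is.na(eligible_practices[1])) {
    # practice restriction disabled
  } else {
    nt <- nt[practice_id %in% eligible_practices]
  }
  if (!is.null(start_year)) {
    nt <- nt[offset_year(date, origin_date) >= start_year]
  }
  if (nrow(nt) == 0L) return(empty)

  low <- tolower(nt$text)
  matched <- rep(NA_character_, nrow(nt))
  pos <- rep(NA_integer_, nrow(nt))
  for (trig in code_sets$free_text$triggers) {
    ok <- rep(TRUE, nrow(nt))
    for (piece in trig) ok <- ok & grepl(piece, low, fixed = TRUE)
    new_hit <- ok & is.na(matched)
    if (any(new_hit)) {
      matched[new_hit] <- paste(trig, collapse = " + ")
      pos[new_hit] <- regexpr(trig[1], low[new_hit], fixed = TRUE)
    }
  }
  hit <- !is.na(matched)
  if (!any(hit)) return(empty)
  nt <- nt[hit]
  low <- low[hit]
  pos <- pos[hit]
  ctx_start <- pmax(pos - 500L, 1L)
  ctx_end <- pmin(pos + nchar(matched[hit]) + 500L, nchar(low))
  context <- substr(nt$text, ctx_start, ctx_end)
  excl <- rep(FALSE, nrow(nt))
  for (phrase in code_sets$free_text$exclusions) {
    excl <- excl | grepl(phrase, low, fixed = TRUE)
  }
  data.table::data.table(
    patient_id = nt$patient_id, date = nt$date,
    matched_string = matched[hit], context = context,
    verdict = data.table::fifelse(excl, "not_scd", "scd"))
}

#' Sudden-cardiac-death tier flags
#'
#' Vectorised evaluation of the three nested case definitions. The primary
#' (narrow) tier requires evidence in the restrictive code set — death
#' certificate, matching primary-care code, or a qualifying free-text match
#' — and no hospital discharge in the 30 days before death (an in-hospital
#' death also disqualifies). The secondary (broad) tier uses the wider code
#' set with a hospitalisation exclusion whose window is configurable. The
#' tertiary tier requires a primary-care record in the broad set and uses
#' neither death certificates nor hospital data.
#'
#' @param cert_in_primary,cert_in_secondary death-certificate code in the
#'   respective set.
#' @param read_in_primary,read_in_secondary a primary-care record in the
#'   respective set.
#' @param ft_scd qualifying free-text match (`scd` verdict).
#' @param hosp_excl_primary,hosp_excl_secondary hospitalisation
#'   disqualifiers for the two tiers.
#' @return `data.table` with logical columns `scd_primary`,
#'   `scd_secondary`, `scd_tertiary`.
#' @export
scd_tier_flags <- function(cert_in_primary, cert_in_secondary,
                           read_in_primary, read_in_secondary,
                           ft_scd, hosp_excl_primary, hosp_excl_secondary) {
  data.table::data.table(
    scd_primary = (cert_in_primary | read_in_primary | ft_scd) &
      !hosp_excl_primary,
    scd_secondary = (cert_in_secondary | read_in_secondary | ft_scd) &
      !hosp_excl_secondary,
    scd_tertiary = read_in_secondary)
}

#' Adjudicate outcomes across record sources
#'
#' For each subject and outcome, finds the qualifying record using the
#' source-precedence hierarchy (death certificate, then free text, then
#' primary-care code) and resolves the event date: the certificate uses the
#' recorded death date; a free-text match uses the earlier of the death
#' date and the note date; a primary-care code uses the earlier of the
#' death date and the code date; when both free text and a primary-care
#' code are present (and no certificate evidence), the earlier of the two
#' resolved dates is used with free text as the winning source. Deaths with
#' a suicide-coded certificate are excluded from all-cause mortality but
#' still censor follow-up. Nonfatal outcomes (CHD, ventricular arrhythmia)
#' take the earliest qualifying primary-care or hospital record.
#'
#' @param subjects cohort table ([identify_users()] and friends, stacked).
#' @param events coded events table.
#' @param ft_matches free-text matches from [search_free_text()].
#' @param patients patients table.
#' @param code_sets packaged code sets.
#' @param secondary_hosp_mode hospitalisation exclusion window for the
#'   broad sudden-cardiac-death definition: an episode overlapping the 30
#'   days before death (default) or any episode during follow-up.
#' @param read_death_window days around death within which a primary-care
#'   mortality code is attributed to the death.
#' @return `data.table` with one row per subject-outcome event:
#'   `patient_id`, `cohort`, `outcome`, `event_date`, `winning_source`.
#' @export
adjudicate_outcomes <- function(subjects, events, ft_matches, patients,
                                code_sets = load_code_sets(),
                                secondary_hosp_mode = c("pre_death_30d",
                                                        "any_followup"),
                                read_death_window = 30) {
  secondary_hosp_mode <- match.arg(secondary_hosp_mode)
  subj <- merge(subjects,
                patients[, .(patient_id, death_date)], by = "patient_id")

  certs <- events[source == "death_certificate",
                  .(cert_code = code[1L]), by = patient_id]
  subj <- merge(subj, certs, by = "patient_id", all.x = TRUE)
  subj[, died := !is.na(death_date) & death_date <= censor_date &
         death_date > index_date]
  subj[, suicide := died & !is.na(cert_code) &
         icd_match(cert_code, code_sets$icd10$suicide)]

  out <- list()

  # all-cause mortality (excluding suicide)
  ac <- subj[died & !suicide]
  out$all_cause <- ac[, .(patient_id, cohort, outcome = "all_cause_mortality",
                          event_date = death_date,
                          winning_source = "death_certificate")]

  # cardiac mortality from death certificates
  cm <- subj[died & !is.na(cert_code) &
               icd_match(cert_code, code_sets$icd10$cardiac_mortality)]
  out$cardiac <- cm[, .(patient_id, cohort, outcome = "cardiac_mortality",
                        event_date = death_date,
                        winning_source = "death_certificate")]

  # sudden cardiac death, three tiers
  out <- c(out, adjudicate_scd(subj, events, ft_matches, code_sets,
                               secondary_hosp_mode, read_death_window))

  # nonfatal outcomes: earliest qualifying record in follow-up
  for (oc in c("chd", "ventricular_arrhythmia")) {
    qual <- rbind(
      events[source == "primary_care" &
               read_match(code, code_sets$primary_care[[oc]]),
             .(patient_id, date, src = "primary_care")],
      events[source == "hospital" &
               icd_match(code, code_sets$icd10[[oc]]),
             .(patient_id, date, src = "hospital")])
    m <- qual[subj, on = "patient_id", nomatch = NULL, allow.cartesian = TRUE]
    m <- m[date >= index_date & date <= censor_date]
    data.table::setorder(m, patient_id, cohort, date,
                         -src)  # primary_care before hospital on ties
    first <- m[, .SD[1L], by = .(patient_id, cohort)]
    out[[oc]] <- first[, .(patient_id, cohort, outcome = oc,
                           event_date = date, winning_source = src)]
  }

  res <- data.table::rbindlist(out, use.names = TRUE)
  data.table::setorder(res, patient_id, cohort, outcome, event_date)
  res[]
}

adjudicate_scd <- function(subj, events, ft_matches, code_sets,
                           secondary_hosp_mode, read_death_window) {
  cs <- code_sets
  dd <- subj[died == TRUE]
  if (nrow(dd) == 0L) {
    return(list(scd = data.table::data.table(
      patient_id = integer(), cohort = character(), outcome = character(),
      event_date = numeric(), winning_source = character())))
  }

  # primary-care mortality-code evidence near death
  pc <- events[source == "primary_care"]
  pc_p <- pc[read_match(code, cs$primary_care$scd_primary)]
  pc_s <- pc[read_match(code, cs$primary_care$scd_secondary)]
  near <- function(ev) {
    m <- ev[dd, on = "patient_id", nomatch = NULL, allow.cartesian = TRUE]
    m <- m[abs(date - death_date) <= read_death_window]
    m[, .(read_date = min(date)), by = .(patient_id, cohort)]
  }
  rp <- near(pc_p)
  rs <- near(pc_s)
  dd[, `:=`(read_date_primary = NA_real_, read_date_secondary = NA_real_,
            hosp30 = FALSE, hosp_sec = FALSE)]
  if (nrow(rp)) {
    dd[rp, on = .(patient_id, cohort), read_date_primary := i.read_date]
  }
  if (nrow(rs)) {
    dd[rs, on = .(patient_id, cohort), read_date_secondary := i.read_date]
  }

  # qualifying free-text matches
  dd[, ft_date := NA_real_]
  if (nrow(ft_matches)) {
    ft <- ft_matches[verdict == "scd",
                     .(ft_date = min(date)), by = patient_id]
    if (nrow(ft)) dd[ft, on = "patient_id", ft_date := i.ft_date]
  }

  # hospitalisation disqualifiers
  hosp <- events[source == "hospital" & !is.na(discharge_date)]
  h30 <- hosp[dd, on = "patient_id", nomatch = NULL, allow.cartesian = TRUE]
  h30 <- h30[admission_date <= death_date &
               discharge_date >= death_date - 30,
             .(excl = TRUE), by = .(patient_id, cohort)]
  if (nrow(h30)) dd[h30, on = .(patient_id, cohort), hosp30 := TRUE]
  if (secondary_hosp_mode == "any_followup") {
    hf <- hosp[dd, on = "patient_id", nomatch = NULL,
               allow.cartesian = TRUE]
    hf <- hf[admission_date >= index_date & admission_date <= death_date,
             .(excl = TRUE), by = .(patient_id, cohort)]
    if (nrow(hf)) dd[hf, on = .(patient_id, cohort), hosp_sec := TRUE]
  } else {
    dd[, hosp_sec := hosp30]
  }

  flags <- scd_tier_flags(
    cert_in_primary = !is.na(dd$cert_code) &
      icd_match(dd$cert_code, cs$icd10$scd_primary),
    cert_in_secondary = !is.na(dd$cert_code) &
      icd_match(dd$cert_code, cs$icd10$scd_secondary),
    read_in_primary = !is.na(dd$read_date_primary),
    read_in_secondary = !is.na(dd$read_date_secondary),
    ft_scd = !is.na(dd$ft_date),
    hosp_excl_primary = dd$hosp30,
    hosp_excl_secondary = dd$hosp_sec)

  tier_rows <- function(tier, cert_ok, read_dates) {
    take <- flags[[tier]]
    if (tier == "scd_tertiary") {
      rows <- dd[take]
      rows[, `:=`(event_date = pmin(death_date, read_date_secondary),
                  winning_source = "primary_care")]
    } else {
      rows <- dd[take]
      cert_e <- cert_ok[take]
      rd <- read_dates[take]
      ftd <- rows$ft_date
      # hierarchy: certificate, then free text, then primary-care code
      src <- data.table::fifelse(
        cert_e, "death_certificate",
        data.table::fifelse(!is.na(ftd), "free_text", "primary_care"))
      edate <- rows$death_date
      ft_res <- pmin(rows$death_date, ftd, na.rm = TRUE)
      rc_res <- pmin(rows$death_date, rd, na.rm = TRUE)
      both <- !is.na(ftd) & !is.na(rd)
      edate[src == "free_text"] <- ft_res[src == "free_text"]
      edate[src == "free_text" & both] <-
        pmin(ft_res, rc_res)[src == "free_text" & both]
      edate[src == "primary_care"] <- rc_res[src == "primary_care"]
      rows[, `:=`(event_date = edate, winning_source = src)]
    }
    rows <- rows[event_date >= index_date & event_date <= censor_date]
    rows[, .(patient_id, cohort, outcome = tier, event_date,
             winning_source)]
  }

  list(
    scd_primary = tier_rows("scd_primary",
                            !is.na(dd$cert_code) &
                              icd_match(dd$cert_code, cs$icd10$scd_primary),
                            dd$read_date_primary),
    scd_secondary = tier_rows("scd_secondary",
                              !is.na(dd$cert_code) &
                                icd_match(dd$cert_code,
                                          cs$icd10$scd_secondary),
                              dd$read_date_secondary),
    scd_tertiary = tier_rows("scd_tertiary", NULL, NULL))
}
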