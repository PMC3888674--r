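#' Hand-crafted adjudication fixture
#'
#' A packaged set of synthetic subjects, each exercising one adjudication
#' rule: the source-precedence hierarchy, earlier-date resolution, suicide
#' exclusion from all-cause mortality, the 30-day post-discharge rule of
#' the narrow sudden-cardiac-death definition, tier nesting, the three-week
#' free-text window, and the exclusion-phrase verdicts. Every subject has
#' registration at day -1000, data collection from day -500, index day 0
#' and (where they die) death at day 300; expectations are frozen alongside
#' the records.
#'
#' @return list with `patients`, `events`, `freetext`, `subjects` and
#'   `expected` (`patient_id`, `outcome`, `event`, `source`, `event_date`).
#' @export
adjudication_fixture <- function() {
  pts <- list(); evs <- list(); nts <- list(); exp <- list()
  nid <- 0L

  new_subject <- function(death = 300) {
    nid <<- nid + 1L
    pts[[nid]] <<- data.table::data.table(
      patient_id = nid, practice_id = 1L, sex = "F", birth_year = 1940L,
      registration_date = -1000, data_start = -500,
      transfer_out = NA_real_, death_date = death)
    nid
  }
  ev <- function(id, date, source, code, adm = NA_real_, dis = NA_real_) {
    evs[[length(evs) + 1L]] <<- data.table::data.table(
      patient_id = id, date = date, source = source, code = code,
      admission_date = adm, discharge_date = dis)
  }
  note <- function(id, date, text) {
    nts[[length(nts) + 1L]] <<- data.table::data.table(
      patient_id = id, practice_id = 1L, date = date, text = text,
      truth_label = NA_character_)
  }
  expect <- function(id, outcome, event, source = NA_character_,
                     date = NA_real_) {
    exp[[length(exp) + 1L]] <<- data.table::data.table(
      patient_id = id, outcome = outcome, event = event, source = source,
      event_date = date)
  }

  # 1: certificate evidence alone (narrow set) wins as death_certificate
  id <- new_subject(); ev(id, 300, "death_certificate", "I46")
  expect(id, "scd_primary", TRUE, "death_certificate", 300)
  expect(id, "scd_secondary", TRUE, "death_certificate", 300)
  expect(id, "cardiac_mortality", TRUE, "death_certificate", 300)
  expect(id, "scd_tertiary", FALSE)

  # 2: hierarchy - certificate beats primary-care code and free text
  id <- new_subject(); ev(id, 300, "death_certificate", "I46")
  ev(id, 297, "primary_care", "RC_I46")
  note(id, 295, "patient died suddenly at home")
  expect(id, "scd_primary", TRUE, "death_certificate", 300)
  expect(id, "scd_tertiary", TRUE, "primary_care", 297)

  # 3: primary-care code qualifies without free-text support; date is the
  # earlier of code date and death date
  id <- new_subject(); ev(id, 300, "death_certificate", "C34")
  ev(id, 298, "primary_care", "RC_I46")
  expect(id, "scd_primary", TRUE, "primary_care", 298)
  expect(id, "cardiac_mortality", FALSE)

  # 4: free-text-only case
  id <- new_subject(); ev(id, 300, "death_certificate", "C34")
  note(id, 295, "collapsed, sudden cardiac death suspected")
  expect(id, "scd_primary", TRUE, "free_text", 295)

  # 5: free text and primary-care code both present, no certificate
  # evidence: free text wins the source, the earlier resolved date is used
  id <- new_subject(); ev(id, 300, "death_certificate", "C34")
  note(id, 299, "died suddenly overnight")
  ev(id, 296, "primary_care", "RC_I46")
  expect(id, "scd_primary", TRUE, "free_text", 296)

  # 6: suicide-coded death is excluded from all-cause mortality
  id <- new_subject(); ev(id, 300, "death_certificate", "X70")
  expect(id, "all_cause_mortality", FALSE)
  expect(id, "cardiac_mortality", FALSE)

  # 7: non-suicide death counts for all-cause mortality
  id <- new_subject(); ev(id, 300, "death_certificate", "C34")
  expect(id, "all_cause_mortality", TRUE, "death_certificate", 300)

  # 8: discharge 20 days before death blocks the narrow definition
  id <- new_subject(); ev(id, 300, "death_certificate", "I46")
  ev(id, 270, "hospital", "J18", adm = 260, dis = 280)
  expect(id, "scd_primary", FALSE)
  expect(id, "scd_secondary", FALSE)

  # 9: discharge 45 days before death does not
  id <- new_subject(); ev(id, 300, "death_certificate", "I46")
  ev(id, 245, "hospital", "J18", adm = 235, dis = 255)
  expect(id, "scd_primary", TRUE, "death_certificate", 300)
  expect(id, "scd_secondary", TRUE, "death_certificate", 300)

  # 10: broad-set-only certificate code: secondary yes, primary no
  id <- new_subject(); ev(id, 300, "death_certificate", "R98")
  expect(id, "scd_primary", FALSE)
  expect(id, "scd_secondary", TRUE, "death_certificate", 300)

  # 11: hierarchical ICD matching - I47.2 via the I47 block entry
  id <- new_subject(); ev(id, 300, "death_certificate", "I47.2")
  expect(id, "scd_primary", TRUE, "death_certificate", 300)
  expect(id, "scd_secondary", TRUE, "death_certificate", 300)

  # 12: I47.0 is in the broad block but not the narrow set
  id <- new_subject(); ev(id, 300, "death_certificate", "I47.0")
  expect(id, "scd_primary", FALSE)
  expect(id, "scd_secondary", TRUE, "death_certificate", 300)

  # 13: certificate-only case never satisfies the primary-care-only tier
  id <- new_subject(); ev(id, 300, "death_certificate", "R96.1")
  expect(id, "scd_primary", TRUE, "death_certificate", 300)
  expect(id, "scd_tertiary", FALSE)

  # 14: broad-set primary-care code near death satisfies the tertiary tier
  id <- new_subject(); ev(id, 300, "death_certificate", "C34")
  ev(id, 301, "primary_care", "RC_I21")
  expect(id, "scd_tertiary", TRUE, "primary_care", 300)
  expect(id, "scd_primary", FALSE)

  # 15: note just inside the three-week window matches
  id <- new_subject(); ev(id, 300, "death_certificate", "C34")
  note(id, 321, "family report patient dropped dead")
  expect(id, "scd_primary", TRUE, "free_text", 300)

  # 16: note outside the three-week window is ignored
  id <- new_subject(); ev(id, 300, "death_certificate", "C34")
  note(id, 340, "family report patient dropped dead")
  expect(id, "scd_primary", FALSE)

  # 17: exclusion phrase flips the free-text verdict
  id <- new_subject(); ev(id, 300, "death_certificate", "C34")
  note(id, 298, "sudden death following motor vehicle accident")
  expect(id, "scd_primary", FALSE)

  # 18: conjunctive trigger (death + cause unknown)
  id <- new_subject(); ev(id, 300, "death_certificate", "C34")
  note(id, 298, "death at home, cause unknown at present")
  expect(id, "scd_primary", TRUE, "free_text", 298)

  # 19: benign note without trigger strings
  id <- new_subject(); ev(id, 300, "death_certificate", "C34")
  note(id, 298, "passed away peacefully, family present")
  expect(id, "scd_primary", FALSE)

  # 20: nonfatal CHD from a primary-care code
  id <- new_subject(NA_real_); ev(id, 120, "primary_care", "CHD01")
  expect(id, "chd", TRUE, "primary_care", 120)

  # 21: nonfatal CHD from a hospital myocardial-infarction episode
  id <- new_subject(NA_real_)
  ev(id, 150, "hospital", "I21", adm = 150, dis = 156)
  expect(id, "chd", TRUE, "hospital", 150)

  # 22: CHD record before the index date does not count
  id <- new_subject(NA_real_); ev(id, -50, "primary_care", "CHD01")
  expect(id, "chd", FALSE)

  # 23: earliest qualifying CHD record wins
  id <- new_subject(NA_real_)
  ev(id, 200, "primary_care", "CHD01")
  ev(id, 140, "hospital", "I21", adm = 140, dis = 145)
  expect(id, "chd", TRUE, "hospital", 140)

  # 24: ventricular arrhythmia via hospital I49.0
  id <- new_subject(NA_real_)
  ev(id, 90, "hospital", "I49.0", adm = 90, dis = 95)
  expect(id, "ventricular_arrhythmia", TRUE, "hospital", 90)

  # 25: ventricular arrhythmia via primary-care code
  id <- new_subject(NA_real_); ev(id, 75, "primary_care", "VA001")
  expect(id, "ventricular_arrhythmia", TRUE, "primary_care", 75)

  # 26: in-hospital death blocks the narrow definition
  id <- new_subject(); ev(id, 300, "death_certificate", "I46")
  ev(id, 290, "hospital", "I50", adm = 290, dis = 300)
  expect(id, "scd_primary", FALSE)

  # 27: unrelated early hospitalisation does not block the default
  # (30-day-window) broad definition
  id <- new_subject(); ev(id, 300, "death_certificate", "R98")
  ev(id, 100, "hospital", "K35", adm = 100, dis = 104)
  expect(id, "scd_secondary", TRUE, "death_certificate", 300)

  # 28: cardiac mortality from a hypertensive-code certificate
  id <- new_subject(); ev(id, 300, "death_certificate", "I10")
  expect(id, "cardiac_mortality", TRUE, "death_certificate", 300)
  expect(id, "scd_primary", FALSE)

  # 29: tertiary tier needs the code near death, not anywhere
  id <- new_subject(); ev(id, 300, "death_certificate", "C34")
  ev(id, 50, "primary_care", "RC_I21")
  expect(id, "scd_tertiary", FALSE)

  # 30: death after the censor date is outside follow-up
  id <- new_subject(600)
  pts[[id]]$transfer_out <- 200
  ev(id, 600, "death_certificate", "I46")
  expect(id, "scd_primary", FALSE)
  expect(id, "all_cause_mortality", FALSE)

  patients <- data.table::rbindlist(pts)
  patients[, `:=`(.entry = pmax(registration_date, data_start),
                  .end = data.table::fifelse(is.na(transfer_out), 1000,
                                             transfer_out))]
  patients[, .end_fu := pmin(.end, death_date, na.rm = TRUE)]
  subjects <- patients[, .(
    patient_id, cohort = "psych_nonuser", index_date = 0,
    user_type = NA_character_, first_class = NA_character_,
    censor_date = .end_fu, match_group = NA_integer_)]
  list(patients = patients, events = data.table::rbindlist(evs),
       freetext = data.table::rbindlist(nts),
       subjects = subjects, expected = data.table::rbindlist(exp))
}
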