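# Record emission for the simulator: coded events across the three sources
# and short free-text notes near death dates.

DEATH_CODE_POOLS <- list(
  scd = c("I46", "I49.0", "R96.0", "R09.2", "I47.2"),
  cardiac_other = c("I21", "I25", "I20", "I11.9", "I42.9", "I51.9",
                    "I70.9", "R98"),
  other_mortality = c("C34", "J44", "G30", "K70", "E14", "N18", "J18"),
  suicide = c("X60", "X70", "X78", "X64")
)

emit_coded_events <- function(pts, death, nonfatal, cfg) {
  ev <- list()
  blank <- function(n) rep(NA_real_, n)

  # psychiatric diagnoses as primary-care rows
  cs <- load_code_sets()
  for (d in names(cs$primary_care$psych)) {
    col <- paste0("dx_", d)
    rows <- pts[!is.na(get(col)),
                .(patient_id, date = floor(get(col)),
                  source = "primary_care",
                  code = cs$primary_care$psych[[d]],
                  admission_date = NA_real_, discharge_date = NA_real_)]
    ev[[paste0("dx_", d)]] <- rows
  }

  nd <- nrow(death)
  if (nd) {
    cert_code <- character(nd)
    for (cz in names(DEATH_CODE_POOLS)) {
      sel <- death$cause == cz
      cert_code[sel] <- sample(DEATH_CODE_POOLS[[cz]], sum(sel),
                               replace = TRUE)
    }
    ev$death_cert <- data.table::data.table(
      patient_id = death$patient_id, date = death$t,
      source = "death_certificate", code = cert_code,
      admission_date = blank(nd), discharge_date = blank(nd))

    # primary-care mortality codes mirroring the certificate cause
    p_read <- data.table::fifelse(
      death$cause == "scd", cfg$scd_read_code_prob,
      data.table::fifelse(death$cause == "cardiac_other",
                          cfg$cardiac_read_code_prob, 0))
    take <- runif(nd) < p_read
    if (any(take)) {
      dd <- death[take]
      rc_date <- floor(dd$t + runif(nrow(dd), -2, 5))
      dd_entry <- pts[dd, on = "patient_id", .entry]
      ev$death_read <- data.table::data.table(
        patient_id = dd$patient_id,
        date = pmax(rc_date, floor(dd_entry) + 1),
        source = "primary_care", code = as_read_code(cert_code[take]),
        admission_date = blank(nrow(dd)), discharge_date = blank(nrow(dd)))
    }

    # hospital episode ending shortly before death
    hosp <- runif(nd) < cfg$hospitalised_death_fraction
    if (any(hosp)) {
      dh <- death[hosp]
      dh_reg <- pts[dh, on = "patient_id", registration_date]
      adm <- pmax(floor(dh$t - runif(nrow(dh), 5, 70)),
                  floor(dh_reg) + 1)
      dis <- pmin(floor(adm + runif(nrow(dh), 1, 20)), dh$t - 1)
      keep <- adm < dis
      dh <- dh[keep]; adm <- adm[keep]; dis <- dis[keep]
      ev$death_hosp <- data.table::data.table(
        patient_id = dh$patient_id, date = adm, source = "hospital",
        code = sample(c("J18", "I50", "N39", "I63"), nrow(dh),
                      replace = TRUE),
        admission_date = adm, discharge_date = dis)
    }
  }

  # nonfatal outcome events: primary-care code and/or hospital episode
  nf_spec <- list(
    chd = list(read = "CHD01", icd = "I21", p_read = 0.7, p_hosp = 0.8),
    ventricular_arrhythmia = list(read = "VA001", icd = "I49.0",
                                  p_read = 0.7, p_hosp = 0.6))
  for (oc in names(nf_spec)) {
    tab <- nonfatal[[oc]]
    if (is.null(tab) || nrow(tab) == 0L) next
    sp <- nf_spec[[oc]]
    n <- nrow(tab)
    r <- runif(n) < sp$p_read
    h <- runif(n) < sp$p_hosp
    # guarantee at least one source records the event
    r <- r | !h
    if (any(r)) {
      ev[[paste0(oc, "_read")]] <- data.table::data.table(
        patient_id = tab$patient_id[r], date = tab$t[r],
        source = "primary_care", code = sp$read,
        admission_date = blank(sum(r)), discharge_date = blank(sum(r)))
    }
    if (any(h)) {
      dis <- floor(tab$t[h] + runif(sum(h), 2, 10))
      ev[[paste0(oc, "_hosp")]] <- data.table::data.table(
        patient_id = tab$patient_id[h], date = tab$t[h],
        source = "hospital", code = sp$icd,
        admission_date = tab$t[h], discharge_date = dis)
    }
  }

  # background hospital admissions unrelated to the outcomes
  fu_years <- (pts$.end_fu - pts$.entry) / DAYS_PER_YEAR
  n_adm <- stats::rpois(nrow(pts), cfg$background_admission_rate *
                          pmax(fu_years, 0))
  if (sum(n_adm)) {
    bg <- pts[rep(seq_len(nrow(pts)), n_adm), .(patient_id, .entry, .end_fu)]
    bg[, adm := floor(.entry + runif(.N) * pmax(.end_fu - .entry - 2, 1))]
    bg[, dis := pmin(floor(adm + runif(.N, 1, 15)), floor(.end_fu))]
    bg <- bg[dis >= adm]
    ev$background <- bg[, .(patient_id, date = adm, source = "hospital",
                            code = sample(c("J18", "K35", "S72", "N39"),
                                          .N, replace = TRUE),
                            admission_date = adm, discharge_date = dis)]
  }

  # exclusion-condition codes (congenital conduction/cardiomyopathy at any
  # time; tachyarrhythmia-set codes spread around registration and index)
  n <- nrow(pts)
  any_t <- runif(n) < cfg$exclusion_condition_rate
  if (any(any_t)) {
    pa <- pts[any_t]
    ev$excl_any <- data.table::data.table(
      patient_id = pa$patient_id,
      date = floor(pa$registration_date +
                     runif(nrow(pa)) * pmax(pa$.end_fu -
                                              pa$registration_date, 1)),
      source = "primary_care",
      code = sample(load_code_sets()$exclusion_conditions$any_time,
                    nrow(pa), replace = TRUE),
      admission_date = blank(nrow(pa)), discharge_date = blank(nrow(pa)))
  }
  pre_i <- runif(n) < cfg$exclusion_condition_rate
  if (any(pre_i)) {
    pa <- pts[pre_i]
    lo <- pa$registration_date - 200
    ev$excl_vt <- data.table::data.table(
      patient_id = pa$patient_id,
      date = floor(lo + runif(nrow(pa)) * pmax(pa$.end_fu - lo, 1)),
      source = "primary_care",
      code = sample(load_code_sets()$exclusion_conditions$pre_index,
                    nrow(pa), replace = TRUE),
      admission_date = blank(nrow(pa)), discharge_date = blank(nrow(pa)))
  }

  out <- data.table::rbindlist(ev, use.names = TRUE)
  data.table::setorder(out, patient_id, date, source)
  out[]
}

SCD_NOTE_TEMPLATES <- c(
  "patient dropped dead at home last night, ambulance called",
  "reported that patient died suddenly in his sleep",
  "relatives describe sudden cardiac death, no prior warning",
  "collapsed and died unexpectedly while shopping",
  "sudden death at home, coroner informed, cause unknown at present",
  "acute cardiac death witnessed by spouse")
OTHER_TRIGGER_TEMPLATES <- c(
  "sudden death following motor vehicle accident on the motorway",
  "died suddenly, suspected overdose of prescribed medication",
  "dropped dead after road traffic accident, coroner involved",
  "died unexpectedly, terminal care for metastatic disease documented")
BENIGN_TEMPLATES <- c(
  "passed away peacefully with family present",
  "deceased following long illness, district nurse informed",
  "family notified practice of the passing of the patient",
  "expected demise after palliative input")

emit_freetext <- function(pts, death, cfg) {
  empty <- data.table::data.table(
    patient_id = integer(), practice_id = integer(), date = numeric(),
    text = character(), truth_label = character())
  if (nrow(death) == 0L) return(empty)
  set_rows <- runif(nrow(death)) < cfg$free_text_note_prob
  dd <- death[set_rows]
  if (nrow(dd) == 0L) return(empty)
  dd <- merge(dd, pts[, .(patient_id, practice_id)], by = "patient_id")
  n <- nrow(dd)
  dd[, date := floor(t + runif(n, -5, 8))]

  is_scd <- dd$cause == "scd"
  kind <- character(n)
  kind[is_scd] <- "scd"
  kind[!is_scd] <- ifelse(runif(sum(!is_scd)) < 0.25, "excluded", "benign")
  core <- character(n)
  core[kind == "scd"] <- sample(SCD_NOTE_TEMPLATES, sum(kind == "scd"),
                                replace = TRUE)
  core[kind == "excluded"] <- sample(OTHER_TRIGGER_TEMPLATES,
                                     sum(kind == "excluded"), replace = TRUE)
  core[kind == "benign"] <- sample(BENIGN_TEMPLATES, sum(kind == "benign"),
                                   replace = TRUE)

  # practice-level verbosity drives the free-text volume eligibility rule
  verbosity <- stats::rlnorm(cfg$n_practices, 0, 0.6)
  pad <- strrep("routine entry recorded. ",
                pmin(round(verbosity[dd$practice_id] *
                             runif(n, 0.5, 3) * 4), 40))
  dd[, text := paste0(pad, core, ". ", pad)]
  dd[, truth_label := ifelse(kind == "scd", "true_scd", "other_cause")]
  dd[, .(patient_id, practice_id, date, text, truth_label)]
}
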