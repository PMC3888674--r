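#' Generate antipsychotic prescribing histories
#'
#' Assigns treatment among psychiatric patients (with configurable
#' confounder shifts on the assignment odds), then emits repeat-prescription
#' sequences with stochastic gaps straddling the 30.4-day grace period, drug
#' switching, patient-level chlorpromazine-equivalent dose targets spanning
#' the low/medium/high bands, and field missingness to exercise downstream
#' imputation.
#'
#' Hidden columns `.true_duration`, `.true_cpz` and `.true_class` carry the
#' simulation truth (pre-missingness) used by [generate_outcomes()]; they
#' are dropped when writing tables and must not be consumed by the analysis
#' pipeline.
#'
#' @param pts population from [generate_population()].
#' @param cfg the [sim_config()].
#' @return a `data.table` of prescriptions.
#' @export
generate_prescribing <- function(pts, cfg) {
  set.seed(stage_seed(cfg, "prescribing"))
  drugs <- antipsychotic_drugs()
  m <- nrow(pts)

  lp <- stats::qlogis(cfg$treatment_given_psych) +
    confounder_shift(pts, cfg$confounder_effects, "treat")
  treated <- pts$.psych & runif(m) < stats::plogis(lp)
  tr <- pts[treated]
  if (nrow(tr) == 0L) return(empty_prescriptions())
  nt <- nrow(tr)
  tr[, first_dx := pmin(dx_schizophrenia, dx_bipolar, dx_major_depression,
                        dx_dementia, na.rm = TRUE)]
  tr[, rx_start := pmin(first_dx + rexp(nt, 1 / 180), .end - 45)]
  band <- sample(names(cfg$dose_band_probs), nt, replace = TRUE,
                 prob = cfg$dose_band_probs)
  tr[, dose_band_target := band]
  tr[, n_rx := 1L + stats::rpois(nt, max(cfg$mean_rx_count - 1, 0.5))]

  long <- tr[rep(seq_len(nt), n_rx),
             .(patient_id, rx_start, .end, dose_band_target)]
  long[, j := seq_len(.N), by = patient_id]
  N <- nrow(long)

  long[, duration := sample(c(28, 56), N, replace = TRUE,
                            prob = c(0.8, 0.2))]
  gap_type <- sample(names(cfg$rx_gap_profile), N, replace = TRUE,
                     prob = cfg$rx_gap_profile)
  # the continuous upper bound leaves a one-day margin: emitted dates are
  # floored to whole days, which can stretch a drawn gap by up to a day
  long[, gap := data.table::fcase(
    gap_type == "continuous", runif(N, -14, DAYS_PER_MONTH - 1.1),
    gap_type == "recent_break", runif(N, DAYS_PER_MONTH + 1, 150),
    gap_type == "long_break", runif(N, 160, 500))]
  # start_j = expected end of the previous prescription + drawn gap
  long[, date := rx_start +
         cumsum(data.table::shift(duration, fill = 0) +
                  data.table::shift(gap, fill = 0)),
       by = patient_id]
  long <- long[date <= .end - 1]

  # drug choice: set at the first prescription and at occasional switches,
  # carried forward in between
  long[, switch_pt := j == 1L | runif(.N) < 0.10]
  np <- sum(long$switch_pt)
  cls <- ifelse(runif(np) < cfg$typical_fraction, "typical", "atypical")
  pools <- split(drugs$drug_name, drugs$drug_class)
  picked <- vapply(cls, function(cl) {
    pool <- pools[[cl]]
    pool[sample.int(length(pool), 1L)]
  }, character(1))
  long[, drug_name := NA_character_]
  long[switch_pt == TRUE, drug_name := picked]
  long[, drug_name := {
    i <- cummax(data.table::fifelse(!is.na(drug_name), seq_len(.N), 0L))
    drug_name[i]
  }, by = patient_id]

  band_target <- c(low = 120, medium = 300, high = 520)
  long[, target_cpz := band_target[dose_band_target] * runif(.N, 0.8, 1.2)]
  long <- merge(long, drugs[, .(drug_name, drug_class, cpz_factor)],
                by = "drug_name", sort = FALSE)
  data.table::setorder(long, patient_id, j)
  # tablet strength closest to half the target daily amount (two tablets a
  # day as the prescribing habit), ties to the lower strength
  str_tab <- drugs[, .(strength = strengths[[1L]]), by = drug_name]
  long[, row_id := .I]
  long[, mg_day := target_cpz / cpz_factor]
  cand <- str_tab[long[, .(row_id, drug_name, half = mg_day / 2)],
                  on = "drug_name", allow.cartesian = TRUE]
  cand[, dd := abs(strength - half)]
  data.table::setorder(cand, row_id, dd, strength)
  long[cand[, .(strength = strength[1L]), by = row_id],
       on = "row_id", strength := i.strength]
  long[, prescribed_daily_dose := pmin(pmax(round(mg_day / strength), 1), 6)]
  long[, quantity := prescribed_daily_dose * duration]
  long[, `:=`(.true_duration = duration,
              .true_cpz = prescribed_daily_dose * strength * cpz_factor,
              .true_class = drug_class)]

  # prevalent users: an extra prescription predating data collection
  prev_ok <- runif(nt) < cfg$prevalent_fraction &
    tr$registration_date < tr$data_start - 750
  pv <- tr[prev_ok, .(patient_id, registration_date, data_start)]
  if (nrow(pv)) {
    pre <- long[j == 1L][patient_id %in% pv$patient_id,
                         .(patient_id, drug_name, drug_class, cpz_factor,
                           strength, prescribed_daily_dose)]
    pv <- pv[patient_id %in% pre$patient_id]
    data.table::setorder(pre, patient_id)
    data.table::setorder(pv, patient_id)
    lo <- pmax(pv$registration_date, pv$data_start - 720)
    hi <- pv$data_start - 30
    pre[, date := lo + runif(.N) * (hi - lo)]
    pre[, `:=`(duration = 28, quantity = prescribed_daily_dose * 28, j = 0L,
               .true_duration = 28,
               .true_cpz = prescribed_daily_dose * strength * cpz_factor,
               .true_class = drug_class)]
    long <- rbind(long, pre, fill = TRUE)
  }

  # field missingness (after truth capture)
  N <- nrow(long)
  long[runif(N) < cfg$missing_rates[["quantity"]], quantity := NA_real_]
  long[runif(N) < cfg$missing_rates[["prescribed_daily_dose"]],
       prescribed_daily_dose := NA_real_]
  long[runif(N) < cfg$missing_rates[["strength"]], strength := NA_real_]

  long[, date := floor(date)]
  out <- long[, .(patient_id, date, drug_name, drug_class, quantity,
                  prescribed_daily_dose, strength,
                  .true_duration, .true_cpz, .true_class)]
  data.table::setorder(out, patient_id, date)
  out[]
}

empty_prescriptions <- function() {
  data.table::data.table(
    patient_id = integer(), date = numeric(), drug_name = character(),
    drug_class = character(), quantity = numeric(),
    prescribed_daily_dose = numeric(), strength = numeric(),
    .true_duration = numeric(), .true_cpz = numeric(),
    .true_class = character())
}
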