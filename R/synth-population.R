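#' Generate the synthetic primary-care population
#'
#' Draws patients across practices with registry dates (registration,
#' practice data-collection start, transfer-out), demographics, baseline
#' covariates with configured missingness, and first-record dates for the
#' four psychiatric diagnoses at the configured prevalences. Death dates are
#' assigned later by [generate_outcomes()].
#'
#' Columns prefixed with a dot (`.entry`, `.end`) are derived bookkeeping
#' used by the other generator stages; they are dropped when tables are
#' written to disk.
#'
#' @param cfg a [sim_config()].
#' @return a `data.table`, one row per patient.
#' @export
generate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  validate_sim_config(cfg)
  set.seed(stage_seed(cfg, "population"))
  n <- cfg$n_patients
  H <- cfg$horizon_years * DAYS_PER_YEAR

  practice_start <- runif(cfg$n_practices, -4 * DAYS_PER_YEAR,
                          1.5 * DAYS_PER_YEAR)
  pts <- data.table::data.table(
    patient_id = seq_len(n),
    practice_id = sample.int(cfg$n_practices, n, replace = TRUE)
  )
  pts[, data_start := pmin(practice_start[practice_id], 0)]
  # practices starting collection after the origin keep their late start
  late <- practice_start > 0
  pts[late[practice_id], data_start := practice_start[practice_id]]

  pts[, sex := ifelse(runif(n) < 0.58, "F", "M")]
  age0 <- pmin(pmax(rnorm(n, 60, 22), 18), 95)
  origin_year <- as.integer(format(cfg$origin_date, "%Y"))
  pts[, birth_year := as.integer(origin_year - floor(age0))]

  early <- runif(n) < 0.7
  pts[, registration_date := data.table::fifelse(
    early,
    data_start - runif(n, 0, 20 * DAYS_PER_YEAR),
    data_start + runif(n, 0, 0.6 * pmax(H - data_start, 1)))]
  pts[, .entry := pmax(registration_date, data_start)]

  transfers <- runif(n) < 0.15
  t_out <- pts$.entry + rexp(n, 1 / (6 * DAYS_PER_YEAR))
  pts[, transfer_out := data.table::fifelse(transfers & t_out < H,
                                            t_out, NA_real_)]
  pts[, .end := pmin(data.table::fifelse(is.na(transfer_out), H,
                                         transfer_out), H)]
  # degenerate short records: keep follow-up positive
  pts <- pts[.end > .entry + 1]

  m <- nrow(pts)
  smoke_lv <- c("non", "ex", "current")
  pts[, smoking := sample(smoke_lv, m, replace = TRUE,
                          prob = c(0.5, 0.2, 0.3))]
  pts[runif(m) < cfg$missing_rates[["smoking"]], smoking := NA_character_]
  pts[, bmi := round(pmin(pmax(rnorm(m, 26, 5), 15), 50), 1)]
  pts[runif(m) < cfg$missing_rates[["bmi"]], bmi := NA_real_]

  # psychiatric first-record dates, placed inside follow-up so the
  # diagnosis-indexed cohort accrues person-time
  for (d in c("schizophrenia", "bipolar", "major_depression", "dementia")) {
    col <- paste0("dx_", d)
    has <- runif(m) < cfg$psych_prevalence[[d]]
    lo <- pts$.entry + 30
    hi <- pmax(lo + 1, pts$.end - 90)
    pts[, (col) := data.table::fifelse(has, lo + runif(m) * (hi - lo),
                                       NA_real_)]
  }
  pts[, .psych := !is.na(dx_schizophrenia) | !is.na(dx_bipolar) |
        !is.na(dx_major_depression) | !is.na(dx_dementia)]

  pts[, alcohol_drug_abuse := as.integer(runif(m) < 0.06)]
  pts[, diabetes := as.integer(runif(m) < 0.07)]
  pts[, suicide_attempt := as.integer(runif(m) < 0.03)]
  pts[, deprivation := sample.int(5L, m, replace = TRUE)]
  pts[, prior_psych_admission := as.integer(
    runif(m) < data.table::fifelse(.psych, 0.10, 0.01))]
  pts[, antidepressant := as.integer(
    runif(m) < data.table::fifelse(.psych, 0.5, 0.06))]
  pts[, anxiolytic := as.integer(
    runif(m) < data.table::fifelse(.psych, 0.12, 0.02))]
  pts[, death_date := NA_real_]
  data.table::setkey(pts, patient_id)
  pts[]
}

# covariate design values used by both the treatment-assignment and
# outcome-hazard sides of the confounding machinery
confounder_design <- function(pts) {
  list(
    alcohol_drug_abuse = pts$alcohol_drug_abuse,
    diabetes = pts$diabetes,
    suicide_attempt = pts$suicide_attempt,
    prior_psych_admission = pts$prior_psych_admission,
    smoking_current = as.integer(!is.na(pts$smoking) &
                                   pts$smoking == "current")
  )
}

confounder_shift <- function(pts, effects, side) {
  shift <- numeric(nrow(pts))
  if (!length(effects)) return(shift)
  x <- confounder_design(pts)
  for (nm in names(effects)) {
    shift <- shift + effects[[nm]][[side]] * x[[nm]]
  }
  shift
}
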