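plain_subjects <- function(n, index = 0, censor = 0 + 2 * 365.25,
                           birth_year = 1950L, exposure = "ref") {
  data.table::data.table(
    patient_id = seq_len(n), cohort = "psych_nonuser", index_date = index,
    censor_date = censor, birth_day = (birth_year - 2000) * 365.25,
    sex = "F", exposure = exposure, user_type = NA_character_,
    first_class = NA_character_, match_group = NA_integer_)
}

no_events <- data.table::data.table(
  patient_id = integer(), cohort = character(), outcome = character(),
  event_date = numeric(), winning_source = character())

test_that("person-time accumulates exactly and splits at age-band
           birthdays", {
  su <- plain_subjects(1)
  cells <- accumulate_person_time(su, empty_tl(), no_events,
                                  "all_cause_mortality")
  expect_equal(cells$person_years, 2, tolerance = 1e-12)
  expect_equal(cells$events, 0L)

  # subject crosses an age-band birthday mid-follow-up: two cells whose
  # person-time sums to the total
  su2 <- plain_subjects(1, birth_year = 1961L)
  # age at index = 39: crosses 40 after one year
  cells2 <- accumulate_person_time(su2, empty_tl(), no_events,
                                   "all_cause_mortality")
  expect_equal(nrow(cells2), 2L)
  expect_equal(sum(cells2$person_years), 2, tolerance = 1e-12)
  expect_equal(sort(cells2$age_band), c("30-39", "40-49"))
})

test_that("cell totals match a brute-force day-count oracle", {
  set.seed(31)
  n <- 100
  su <- plain_subjects(n)
  su[, index_date := round(runif(n, 0, 2000))]
  su[, censor_date := index_date + round(runif(n, 30, 3000))]
  su[, birth_day := (sample(1915:1985, n, TRUE) - 2000) * 365.25]
  ev <- su[runif(n) < 0.3,
           .(patient_id, cohort,
             outcome = "all_cause_mortality",
             event_date = round(index_date +
                                  runif(.N) * (censor_date - index_date)),
             winning_source = "death_certificate")]
  cells <- accumulate_person_time(su, empty_tl(), ev,
                                  "all_cause_mortality")

  # oracle: classify every half-day of follow-up by age band
  oracle <- list()
  for (i in seq_len(n)) {
    s <- su[i]
    e2 <- min(s$censor_date,
              if (s$patient_id %in% ev$patient_id)
                ev[patient_id == s$patient_id, event_date] else Inf)
    if (e2 <= s$index_date) next
    steps <- seq(s$index_date, e2 - 0.25, by = 0.5)
    band <- age_band_label_pkg((steps - s$birth_day) / 365.25)
    oracle[[i]] <- data.table::data.table(age_band = band, t = 0.5)
  }
  od <- data.table::rbindlist(oracle)[, .(py = sum(t) / 365.25),
                                      by = age_band]
  m <- merge(cells, od, by = "age_band")
  expect_equal(nrow(m), nrow(cells))
  expect_true(all(abs(m$person_years - m$py) <= 1 / 365.25))
  expect_equal(sum(cells$events), nrow(ev))
})

test_that("with no covariates the fitted rate ratio is the closed-form
           crude ratio", {
  set.seed(32)
  for (k in 1:25) {
    cells <- data.table::data.table(
      exposure = c("exposed", "ref"),
      events = rpois(2, lambda = c(40, 60)) + 1L,
      person_years = runif(2, 50, 5000))
    est <- fit_rate_ratio(cells, reference = "ref", adjustment = "crude")
    closed <- (cells$events[1] / cells$person_years[1]) /
      (cells$events[2] / cells$person_years[2])
    expect_equal(est$rr, closed, tolerance = 1e-8)
  }
})

test_that("identical exposed and reference data give a rate ratio of
           exactly one", {
  cells <- data.table::data.table(
    exposure = c("exposed", "ref"), events = c(17L, 17L),
    person_years = c(123.4, 123.4))
  est <- fit_rate_ratio(cells, reference = "ref", adjustment = "crude")
  expect_equal(est$rr, 1, tolerance = 1e-10)
})

test_that("zero events in a compared level yields NC, not an exception", {
  cells <- data.table::data.table(
    exposure = c("exposed", "ref"), events = c(0L, 12L),
    person_years = c(100, 100))
  est <- fit_rate_ratio(cells, reference = "ref")
  expect_true(est$nc)
  expect_true(is.na(est$rr))
  empty_stratum <- stratified_rr(
    data.table::data.table(exposure = c("exposed", "ref"),
                           events = c(5L, 0L), person_years = c(10, 10),
                           dose_band = c("low", NA)),
    by = "dose_band", reference = "ref", adjustment = "crude")
  expect_true(empty_stratum$nc)
})

test_that("the events-per-parameter budget truncates the candidate pool", {
  # 10 events -> budget 2 non-forced parameters regardless of candidates
  set.seed(33)
  n <- 400
  d <- data.table::data.table(
    exposure = rep(c("exposed", "ref"), each = n / 2),
    age_band = sample(c("30-64", "65-79"), n, TRUE),
    sex = sample(c("F", "M"), n, TRUE),
    person_years = 1)
  for (cc in paste0("x", 1:6)) d[, (cc) := rbinom(n, 1L, 0.5)]
  d[, events := 0L]
  d[sample(.N, 10), events := 1L]
  spec <- model_spec(candidates = paste0("x", 1:6))
  kept <- select_covariates(d, spec, reference = "ref")
  expect_lte(length(kept), 2L)
})

test_that("backward elimination drops noise and keeps a strong
           confounder", {
  set.seed(34)
  n <- 4000
  d <- data.table::data.table(
    exposure = rep(c("exposed", "ref"), each = n / 2),
    age_band = "30-64", sex = "F", person_years = 1)
  d[, conf := rbinom(n, 1L, ifelse(exposure == "exposed", 0.7, 0.3))]
  d[, noise := rbinom(n, 1L, 0.5)]
  mu <- exp(log(0.05) + 1.2 * d$conf + 0.4 * (d$exposure == "exposed"))
  d[, events := rpois(n, mu)]
  spec <- model_spec(candidates = c("conf", "noise"))
  kept <- select_covariates(d, spec, reference = "ref")
  expect_true("conf" %in% kept)
  expect_false("noise" %in% kept)
  # adjustment moves the estimate toward the planted effect
  crude <- fit_rate_ratio(d, reference = "ref", adjustment = "crude")
  full <- fit_rate_ratio(d, reference = "ref", adjustment = "full",
                         spec = spec)
  expect_lt(abs(log(full$rr) - 0.4), abs(log(crude$rr) - 0.4))
  expect_equal(full$covariates_retained, "conf")
})

test_that("user person-time is restricted to current exposure", {
  sim <- cached_sim()
  users <- identify_users(sim$patients, sim$prescriptions)
  sf <- subject_frame(users, sim$patients)
  sf[, exposure := "current_use"]
  ep <- prepare_episodes(sim$prescriptions)
  tl <- build_timelines(ep, users[, .(patient_id, censor_date)])
  cells <- accumulate_person_time(sf, tl, no_events,
                                  "all_cause_mortality")
  # total user cell time equals the current-exposure time inside follow-up
  cur <- tl[state == "current"]
  cur <- merge(cur, users[, .(patient_id, index_date, censor_date)],
               by = "patient_id")
  expected <- cur[, sum(pmax(pmin(end, censor_date) -
                               pmax(start, index_date), 0))] / 365.25
  expect_equal(sum(cells$person_years), expected, tolerance = 1e-9)
})
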