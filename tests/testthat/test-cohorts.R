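make_patients <- function(n, practice = 1L, sex = "F", birth_year = 1950L) {
  data.table::data.table(
    patient_id = seq_len(n), practice_id = practice, sex = sex,
    birth_year = birth_year, registration_date = -2000, data_start = -1500,
    transfer_out = NA_real_, death_date = NA_real_,
    dx_schizophrenia = NA_real_, dx_bipolar = NA_real_,
    dx_major_depression = NA_real_, dx_dementia = NA_real_,
    .entry = -1500, .end = 3000, .end_fu = 3000)
}

rx_row <- function(id, date, drug = "haloperidol", cls = "typical") {
  data.table::data.table(patient_id = id, date = date, drug_name = drug,
                         drug_class = cls, quantity = 56,
                         prescribed_daily_dose = 2, strength = 5)
}

test_that("users are indexed at the first in-study prescription", {
  pts <- make_patients(4)
  rx <- rbind(rx_row(1L, 100), rx_row(1L, 400),
              rx_row(2L, -1800), rx_row(2L, 250, "olanzapine", "atypical"),
              rx_row(3L, 50))
  pts[3, `:=`(death_date = 40, .end_fu = 40)]  # dies before index
  users <- identify_users(pts, rx)
  expect_equal(sort(users$patient_id), c(1L, 2L))
  u1 <- users[patient_id == 1L]
  expect_equal(u1$index_date, 100)
  expect_equal(u1$user_type, "incident")
  expect_equal(u1$first_class, "typical")
  u2 <- users[patient_id == 2L]
  # prescription predates the patient's collection start -> prevalent,
  # indexed at the first prescription under observation
  expect_equal(u2$index_date, 250)
  expect_equal(u2$user_type, "prevalent")
  expect_equal(u2$first_class, "atypical")
})

test_that("prescriptions for unknown patients raise a linkage error", {
  pts <- make_patients(2)
  expect_error(identify_users(pts, rx_row(99L, 10)), "unknown patient")
})

test_that("psychiatric nonusers are indexed at diagnosis and censored at
           the first prescription", {
  pts <- make_patients(4)
  pts[1, dx_schizophrenia := 200]
  pts[2, dx_major_depression := 300]
  pts[3, dx_dementia := 700]
  rx <- rbind(rx_row(1L, 500),   # treated after diagnosis: censored there
              rx_row(3L, 600))   # treated before diagnosis: excluded
  nu <- identify_psych_nonusers(pts, rx)
  expect_equal(sort(nu$patient_id), c(1L, 2L))
  expect_equal(nu[patient_id == 1L, .(index_date, censor_date)],
               data.table::data.table(index_date = 200, censor_date = 500))
  expect_equal(nu[patient_id == 2L, censor_date], 3000)
})

test_that("control matching enforces eligibility and the matching ratio", {
  pts <- make_patients(12)
  # user 1; candidates 2..12
  pts[1, dx_schizophrenia := -100]
  pts[2, dx_bipolar := -50]            # psychiatric history: ineligible
  pts[3, birth_year := 1930L]          # outside age tolerance
  pts[4, `:=`(data_start = -100, .entry = -100)]  # < 12 months of data
  pts[5, practice_id := 2L]            # other practice
  pts[6, sex := "M"]                   # other sex
  pts[7, `:=`(death_date = -10, .end_fu = -10)]   # dead before index
  rx <- rbind(rx_row(1L, 0), rx_row(8L, -1800))   # 8 already treated
  users <- identify_users(pts, rx)
  ctrl <- match_controls(users, pts, rx, match_criteria(), seed = 4L)
  expect_equal(nrow(ctrl), 3L)
  expect_true(all(ctrl$patient_id %in% c(9L, 10L, 11L, 12L)))
  expect_true(all(ctrl$index_date == 0))
  expect_true(all(ctrl$match_group == 1L))
  ms <- attr(ctrl, "match_summary")
  expect_equal(ms$n_controls, 3L)
  # a control prescribed later is censored at that prescription
  rx2 <- rbind(rx, rx_row(9L, 800))
  ctrl2 <- match_controls(users, pts, rx2, match_criteria(ratio = 4L),
                          seed = 4L)
  expect_equal(ctrl2[patient_id == 9L, censor_date], 800)
})

test_that("matched controls agree with their user on the matching factors", {
  sim <- cached_sim()
  users <- identify_users(sim$patients, sim$prescriptions)
  ctrl <- match_controls(users, sim$patients, sim$prescriptions,
                         match_criteria(), seed = 2L)
  expect_gt(nrow(ctrl), 0)
  m <- merge(
    merge(ctrl, sim$patients[, .(patient_id, practice_id, sex, birth_year)],
          by = "patient_id"),
    merge(users[, .(match_group = patient_id, u_index = index_date)],
          sim$patients[, .(match_group = patient_id, u_practice = practice_id,
                           u_sex = sex, u_by = birth_year)],
          by = "match_group"),
    by = "match_group")
  expect_true(all(m$practice_id == m$u_practice))
  expect_true(all(m$sex == m$u_sex))
  expect_true(all(abs(m$birth_year - m$u_by) <= 2))
  expect_true(all(m$index_date == m$u_index))
  # ratio respected and controls are never users
  expect_true(all(attr(ctrl, "match_summary")$n_controls <= 3L))
  expect_false(any(ctrl$patient_id %in% users$patient_id))
})

test_that("cardiac exclusion rules hit their date boundaries", {
  pts <- make_patients(5)
  subj <- data.table::data.table(
    patient_id = 1:5, cohort = "user", index_date = 0,
    user_type = "incident", first_class = "typical", censor_date = 1000,
    match_group = NA_integer_)
  ev <- data.table::data.table(
    patient_id = c(1L, 2L, 3L, 4L),
    date = c(900, 0, 5, -2500),
    source = "primary_care",
    code = c("CMYO1", "VTAC1", "VTAC1", "VTAC1"),
    admission_date = NA_real_, discharge_date = NA_real_)
  kept <- apply_exclusions(subj, ev, pts)
  # 1: cardiomyopathy at any time -> out; 2: tachyarrhythmia on the index
  # date -> out; 3: first coded after index -> retained; 4: on/before
  # registration -> out
  expect_equal(sort(kept$patient_id), c(3L, 5L))
  flow <- attr(kept, "exclusion_flow")
  expect_equal(flow[rule == "congenital_conduction_or_cardiomyopathy_any_time",
                    n_subjects], 1L)
})

test_that("orphaned controls leave with their excluded user", {
  pts <- make_patients(3)
  subj <- data.table::data.table(
    patient_id = c(1L, 2L, 3L),
    cohort = c("user", "general_control", "general_control"),
    index_date = 0, user_type = c("incident", NA, NA),
    first_class = c("typical", NA, NA), censor_date = 1000,
    match_group = c(NA_integer_, 1L, 1L))
  ev <- data.table::data.table(patient_id = 1L, date = 10,
                               source = "primary_care", code = "CMYO1",
                               admission_date = NA_real_,
                               discharge_date = NA_real_)
  kept <- apply_exclusions(subj, ev, pts)
  expect_equal(nrow(kept), 0L)
})

test_that("cohort invariants hold on simulated data", {
  sim <- cached_sim()
  users <- identify_users(sim$patients, sim$prescriptions)
  nonusers <- identify_psych_nonusers(sim$patients, sim$prescriptions)
  expect_false(any(nonusers$patient_id %in%
                     users[user_type == "prevalent", patient_id]))
  # incident users have no prescription before their index date
  first_rx <- sim$prescriptions[, .(first = min(date)), by = patient_id]
  inc <- merge(users[user_type == "incident"], first_rx, by = "patient_id")
  expect_true(all(inc$first == inc$index_date))
  # psych nonusers never have a prescription before index
  nu <- merge(nonusers, first_rx, by = "patient_id")
  expect_true(all(nu$first >= nu$index_date))
  # positive follow-up everywhere
  expect_true(all(users$censor_date > users$index_date))
  expect_true(all(nonusers$censor_date > nonusers$index_date))
})
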