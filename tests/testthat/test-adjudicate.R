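run_fixture <- function(mode = "pre_death_30d") {
  fx <- adjudication_fixture()
  ft <- search_free_text(fx$freetext, fx$patients,
                         eligible_practices = NA)
  adj <- adjudicate_outcomes(fx$subjects, fx$events, ft, fx$patients,
                             secondary_hosp_mode = mode)
  list(fx = fx, ft = ft, adj = adj)
}

test_that("the hand-crafted subjects adjudicate to their expected labels", {
  r <- run_fixture()
  for (i in seq_len(nrow(r$fx$expected))) {
    e <- r$fx$expected[i]
    got <- r$adj[patient_id == e$patient_id & outcome == e$outcome]
    info <- sprintf("patient %d / %s", e$patient_id, e$outcome)
    if (e$event) {
      expect_equal(nrow(got), 1L, info = info)
      expect_equal(got$winning_source, e$source, info = info)
      expect_equal(got$event_date, e$event_date, info = info)
    } else {
      expect_equal(nrow(got), 0L, info = info)
    }
  }
})

test_that("the broad-definition hospitalisation window is configurable", {
  r30 <- run_fixture("pre_death_30d")
  rall <- run_fixture("any_followup")
  # subject 27: early unrelated admission; broad tier survives the 30-day
  # window but not the any-hospitalisation reading
  id <- 27L
  expect_equal(nrow(r30$adj[patient_id == id &
                              outcome == "scd_secondary"]), 1L)
  expect_equal(nrow(rall$adj[patient_id == id &
                               outcome == "scd_secondary"]), 0L)
})

test_that("tier nesting holds on code grounds for the packaged sets", {
  cs <- load_code_sets()
  # every primary-set entry is covered by a secondary-set entry (prefix
  # matching), so a primary case is always a secondary case code-wise
  expect_true(all(icd_match(cs$icd10$scd_primary, cs$icd10$scd_secondary)))
  expect_true(all(apcohort:::read_match(cs$primary_care$scd_primary,
                                        cs$primary_care$scd_secondary)))
  # and every adjudicated narrow case is also a broad case
  r <- run_fixture()
  prim <- r$adj[outcome == "scd_primary", patient_id]
  sec <- r$adj[outcome == "scd_secondary", patient_id]
  expect_true(all(prim %in% sec))
})

test_that("permuting record order never changes the adjudication", {
  fx <- adjudication_fixture()
  ft <- search_free_text(fx$freetext, fx$patients, eligible_practices = NA)
  base <- adjudicate_outcomes(fx$subjects, fx$events, ft, fx$patients)
  data.table::setorder(base, patient_id, cohort, outcome)
  set.seed(7)
  for (k in 1:5) {
    ev2 <- fx$events[sample(.N)]
    ft2 <- ft[sample(.N)]
    alt <- adjudicate_outcomes(fx$subjects, ev2, ft2, fx$patients)
    data.table::setorder(alt, patient_id, cohort, outcome)
    expect_equal(alt, base)
  }
})

test_that("free-text context windows are capped at 500 characters each
           side", {
  fx <- adjudication_fixture()
  long_note <- data.table::data.table(
    patient_id = 1L, practice_id = 1L, date = 298,
    text = paste0(strrep("x", 800), " patient died suddenly at home ",
                  strrep("y", 800)),
    truth_label = NA_character_)
  ft <- search_free_text(long_note, fx$patients, eligible_practices = NA)
  expect_equal(nrow(ft), 1L)
  expect_lte(nchar(ft$context),
             1000 + nchar("died suddenly") + nchar(" patient  at home "))
  expect_match(ft$context, "died suddenly")
})

test_that("free-text verdicts are faithful to the trigger and exclusion
           rules on simulated notes", {
  sim <- cached_sim()
  ft <- search_free_text(sim$freetext, sim$patients,
                         eligible_practices = NA)
  labelled <- merge(ft, sim$freetext[, .(patient_id, date, truth_label)],
                    by = c("patient_id", "date"))
  # every note generated from a sudden-death template matches with verdict
  # scd (perfect recall of trigger-bearing true cases) ...
  truth_notes <- sim$freetext[truth_label == "true_scd"]
  hits <- merge(truth_notes, ft[verdict == "scd"],
                by = c("patient_id", "date"))
  expect_equal(nrow(hits), nrow(truth_notes))
  # ... and every matched note carrying an exclusion phrase is not_scd
  cs <- load_code_sets()
  has_excl <- vapply(labelled$patient_id, function(i) FALSE, logical(1))
  low <- tolower(merge(ft, sim$freetext, by = c("patient_id", "date"))$text)
  excl <- rep(FALSE, length(low))
  for (ph in cs$free_text$exclusions) {
    excl <- excl | grepl(ph, low, fixed = TRUE)
  }
  expect_true(all(labelled$verdict[excl] == "not_scd"))
  expect_true(all(labelled$verdict[!excl] == "scd"))
})

test_that("the practice-volume and start-year eligibility rules filter
           notes", {
  sim <- cached_sim()
  elig <- free_text_eligibility(sim$freetext, sim$patients)
  expect_true(length(elig) > 0 &&
                length(elig) < data.table::uniqueN(sim$patients$practice_id))
  ft_all <- search_free_text(sim$freetext, sim$patients,
                             eligible_practices = NA)
  ft_elig <- search_free_text(sim$freetext, sim$patients)
  expect_lt(nrow(ft_elig), nrow(ft_all))
  pr <- merge(ft_elig, sim$freetext[, .(patient_id, date, practice_id)],
              by = c("patient_id", "date"))
  expect_true(all(pr$practice_id %in% elig))
  # notes before the start year vanish
  ft_late <- search_free_text(sim$freetext, sim$patients,
                              eligible_practices = NA, start_year = 2009,
                              origin_date = as.Date("2000-01-01"))
  yr <- 2000 + floor(ft_late$date / 365.25)
  expect_true(all(ft_late$date >= (2009 - 2000) * 365.25 - 366))
  expect_lt(nrow(ft_late), nrow(ft_all))
})
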