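simple_ep <- function(start, duration, ddd = 150, cls = "typical",
                      id = 1L) {
  data.table::data.table(patient_id = id, start = start,
                         duration_days = duration, ddd_mg = ddd,
                         ddd_imputed = FALSE, duration_imputed = FALSE,
                         drug_class = cls,
                         expected_end = start + duration)
}

test_that("the exposure windows follow the grace and recency rules", {
  tl <- build_timeline(simple_ep(0, 28), 400)
  expect_equal(tl$state, c("current", "current", "recent", "past"))
  expect_equal(tl$start, c(0, 28, 58.4, 210.4))
  expect_equal(tl$end, c(28, 58.4, 210.4, 400))

  # repeat inside the grace window stitches into one treatment window
  tl2 <- build_timeline(rbind(simple_ep(0, 28), simple_ep(40, 28)), 400)
  cur <- tl2[state == "current"]
  expect_equal(min(cur$start), 0)
  expect_equal(max(cur$end), 98.4)
  expect_equal(tl2[state == "recent", .(start, end)],
               data.table::data.table(start = 98.4, end = 250.4))

  # a gap of exactly 30.4 days after the expected end is still continuous
  tl3 <- build_timeline(rbind(simple_ep(0, 28), simple_ep(58.4, 28)), 400)
  expect_equal(max(tl3[state == "current", end]), 58.4 + 28 + 30.4)
  expect_true(all(tl3[start < 58.4 + 28, state] == "current"))
})

test_that("a new prescription during past exposure reopens current", {
  tl <- build_timeline(rbind(simple_ep(0, 28), simple_ep(300, 28)), 700)
  expect_equal(tl$state,
               c("current", "current", "recent", "past",
                 "current", "current", "recent", "past"))
  # past truncated exactly at the new prescription
  expect_equal(tl[state == "past", end][1], 300)
})

test_that("person-time is conserved from first prescription to censoring", {
  set.seed(81)
  for (k in 1:50) {
    ep <- random_rx_set()
    censor <- max(ep$expected_end) + runif(1, 50, 600)
    tl <- build_timeline(ep, censor)
    expect_equal(sum(tl$end - tl$start), censor - min(ep$start),
                 tolerance = 1e-9)
    expect_true(all(tl$end > tl$start))
    # disjoint, ordered, contiguous
    expect_true(all(abs(tl$start[-1] - tl$end[-nrow(tl)]) < 1e-9))
  }
})

test_that("cumulative treated duration is non-decreasing and dose bands
           only change at prescription boundaries", {
  set.seed(82)
  for (k in 1:20) {
    ep <- random_rx_set()
    censor <- max(ep$expected_end) + runif(1, 50, 600)
    tl <- build_timeline(ep, censor)
    cur <- tl[state == "current"]
    bands <- match(cur$cum_duration_band, c("<1y", "1-3y", ">3y"))
    expect_true(all(diff(bands) >= 0))
    # dose-band changes coincide with a prescription start or expected end
    chg <- which(cur$dose_band[-1] != cur$dose_band[-nrow(cur)])
    if (length(chg)) {
      boundary_points <- c(ep$start, ep$expected_end)
      expect_true(all(vapply(cur$start[chg + 1], function(t0) {
        any(abs(boundary_points - t0) < 1e-9)
      }, logical(1))))
    }
  }
})

test_that("interval timelines equal the brute-force day scanner", {
  set.seed(83)
  for (k in 1:150) {
    ep <- random_rx_set()
    censor <- max(ep$expected_end) + runif(1, 0, 500)
    expect_true(check_timeline_against_oracle(ep, censor))
  }
})

test_that("recent and past intervals inherit the treatment window's class
           mix", {
  ep <- rbind(simple_ep(0, 28, cls = "typical"),
              simple_ep(20, 28, cls = "atypical"))
  tl <- build_timeline(ep, 500)
  expect_equal(tl[state == "recent", drug_class], "mixed")
  expect_equal(tl[state == "past", drug_class], "mixed")
  expect_true("mixed" %in% tl[state == "current", drug_class])
})

test_that("episodes starting at or after censoring contribute nothing", {
  expect_equal(nrow(build_timeline(simple_ep(100, 28), 100)), 0L)
  tl <- build_timeline(rbind(simple_ep(0, 28), simple_ep(500, 28)), 400)
  expect_true(all(tl$end <= 400))
})
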