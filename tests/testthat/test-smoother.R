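test_that("the hazard grid tallies at-risk time and event placement", {
  # everyone followed exactly 4 years, no events
  g <- build_hazard_grid(rep(4, 50), n_periods = 100L)
  expect_equal(g$at_risk_years, rep(50 * 4 / 100, 100))
  expect_equal(sum(g$events), 0L)

  # a single event lands in the unique half-open period containing it
  g2 <- build_hazard_grid(rep(4, 10), c(1.02, rep(NA, 9)),
                          n_periods = 100L)
  expect_equal(sum(g2$events), 1L)
  expect_equal(which(g2$events == 1L), findInterval(1.02, g2$edges))

  expect_error(build_hazard_grid(rep(1, 5), n_periods = 1L), "n_periods")
  expect_error(build_hazard_grid(rep(1, 5), rep(2, 5)), "beyond follow-up")
})

test_that("the grid equals a brute-force per-day tally", {
  set.seed(61)
  n <- 50
  fu <- runif(n, 0.5, 8)
  et <- ifelse(runif(n) < 0.4, runif(n) * fu, NA)
  g <- build_hazard_grid(fu, et, n_periods = 40L)
  # oracle: accumulate at-risk time in fine steps, assign events directly
  step <- 1 / 3650
  risk <- numeric(40)
  for (i in seq_len(n)) {
    tt <- seq(step / 2, fu[i], by = step)
    idx <- pmin(findInterval(tt, g$edges), 40L)
    risk <- risk + tabulate(idx, 40L) * step
  }
  expect_true(all(abs(risk - g$at_risk_years) < n * step))
  ora_ev <- tabulate(pmin(findInterval(et[!is.na(et)], g$edges), 40L), 40L)
  expect_equal(g$events, ora_ev)
})

test_that("smoothing weights sum to one and constant hazards are
           recovered", {
  set.seed(62)
  n <- 20000
  h <- 0.12
  horizon <- 6
  raw <- rexp(n, h)
  fu <- pmin(raw, horizon)
  et <- ifelse(raw < horizon, raw, NA)
  g <- build_hazard_grid(fu, et, n_periods = 100L)
  # a constant hazard has no smoothing bias, so a wide kernel window is
  # the right design for a tight pointwise check
  sm <- smooth_hazard(g, bandwidth = 15 * g$width)
  interior <- sm[boundary == FALSE]
  expect_gt(nrow(interior), 50)
  expect_true(all(abs(interior$hazard - h) / h < 0.1))
  # pointwise confidence bands cover the truth at most points
  expect_gt(mean(interior$ci_low <= h & interior$ci_high >= h), 0.8)
})

test_that("the smoothed curve is scale-equivariant and zero without
           events", {
  g <- build_hazard_grid(rep(5, 200),
                         c(runif(40, 0, 5), rep(NA, 160)),
                         n_periods = 50L)
  s1 <- smooth_hazard(g)
  g2 <- g
  g2$at_risk_years <- g$at_risk_years * 2
  s2 <- smooth_hazard(g2)
  expect_equal(s2$hazard, s1$hazard / 2, tolerance = 1e-12)

  g0 <- build_hazard_grid(rep(5, 200), n_periods = 50L)
  s0 <- smooth_hazard(g0)
  expect_true(all(s0$hazard == 0))

  expect_error(smooth_hazard(g, bandwidth = 0), "bandwidth")
})

test_that("identical groups give a ratio curve around one and zero-event
           windows are masked", {
  set.seed(63)
  n <- 5000
  make <- function() {
    raw <- rexp(n, 0.08)
    fu <- pmin(raw, 5)
    et <- ifelse(raw < 5, raw, NA)
    build_hazard_grid(fu, et, n_periods = 60L, t_max = 5)
  }
  ra <- hazard_ratio_curve(smooth_hazard(make()), smooth_hazard(make()))
  ok <- ra[masked == FALSE & boundary == FALSE]
  expect_gt(mean(ok$ci_low <= 1 & ok$ci_high >= 1), 0.9)

  # empty denominator region is masked
  ga <- build_hazard_grid(rep(5, 100), c(1.1, 2.2, rep(NA, 98)),
                          n_periods = 20L, t_max = 5)
  gb <- build_hazard_grid(rep(2, 100), rep(NA_real_, 100),
                          n_periods = 20L, t_max = 5)
  rb <- hazard_ratio_curve(smooth_hazard(ga, bandwidth = 0.3),
                           smooth_hazard(gb, bandwidth = 0.3))
  expect_true(all(rb$masked))
  expect_error(hazard_ratio_curve(smooth_hazard(ga),
                                  smooth_hazard(make())),
               "evaluation points")
})
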