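#' Build a hazard grid over time since treatment start
#'
#' Divides follow-up (measured from each subject's start of treatment) into
#' `n_periods` periods of equal length and tallies, per period, the number
#' of outcome events and the at-risk person-time contributed by subjects
#' still under follow-up.
#'
#' @param follow_up per-subject follow-up lengths (years).
#' @param event_time per-subject event time (years from treatment start),
#'   `NA` when no event; events must satisfy `event_time <= follow_up`.
#' @param n_periods number of equal-length periods (>= 2).
#' @param t_max grid span; defaults to the maximum follow-up.
#' @return list of class `hazard_grid` with `edges`, `mid`, `events`,
#'   `at_risk_years` and `width`.
#' @export
build_hazard_grid <- function(follow_up, event_time = rep(NA_real_,
                                                          length(follow_up)),
                              n_periods = 100L, t_max = NULL) {
  if (n_periods < 2L) stop_config("n_periods must be at least 2")
  stopifnot(length(event_time) == length(follow_up))
  if (any(!is.na(event_time) & event_time > follow_up)) {
    stop_config("event beyond follow-up")
  }
  if (is.null(t_max)) t_max <- max(follow_up)
  stopifnot(t_max > 0)
  edges <- seq(0, t_max, length.out = n_periods + 1L)
  width <- t_max / n_periods

  # at-risk time: overlap of [0, follow_up) with each period
  at_risk <- vapply(seq_len(n_periods), function(j) {
    sum(pmax(pmin(follow_up, edges[j + 1L]) - edges[j], 0))
  }, numeric(1))

  ev <- event_time[!is.na(event_time) & event_time <= t_max]
  # half-open periods; an event exactly at t_max lands in the last period
  idx <- pmin(findInterval(ev, edges), n_periods)
  events <- tabulate(idx, nbins = n_periods)

  structure(list(edges = edges, mid = (edges[-1L] + edges[-(n_periods + 1L)]) / 2,
                 events = events, at_risk_years = at_risk, width = width,
                 n_periods = n_periods),
            class = "hazard_grid")
}

epanechnikov <- function(u) 0.75 * pmax(1 - u^2, 0)

#' Kernel-smoothed hazard curve from a hazard grid
#'
#' Smooths the per-period hazard increments (events divided by at-risk
#' person-time, the rate analogue of Nelson-Aalen increments) with a
#' normalised kernel: the smoothing weights at every evaluation point sum
#' to one, so a constant hazard is reproduced without boundary shrinkage.
#' The pointwise variance treats period event counts as Poisson, and the
#' confidence interval is a normal approximation on the log scale.
#' Evaluation points within one bandwidth of either end of the grid are
#' flagged as boundary estimates.
#'
#' @param grid a [build_hazard_grid()] result.
#' @param bandwidth kernel bandwidth in the grid's time units; defaults to
#'   5 period widths.
#' @param kernel kernel name (`"epanechnikov"` or `"uniform"`).
#' @param eval_points evaluation times; default the period midpoints.
#' @param conf_level confidence level.
#' @return `data.table` with `time`, `hazard`, `se_log`, `ci_low`,
#'   `ci_high`, `boundary`.
#' @export
smooth_hazard <- function(grid, bandwidth = NULL,
                          kernel = c("epanechnikov", "uniform"),
                          eval_points = NULL, conf_level = 0.95) {
  stopifnot(inherits(grid, "hazard_grid"))
  kernel <- match.arg(kernel)
  if (is.null(bandwidth)) bandwidth <- 5 * grid$width
  if (bandwidth <= 0) stop_config("bandwidth must be positive")
  if (is.null(eval_points)) eval_points <- grid$mid
  kf <- switch(kernel, epanechnikov = epanechnikov,
               uniform = function(u) 0.5 * (abs(u) <= 1))

  ok <- grid$at_risk_years > 0
  rate <- ifelse(ok, grid$events / grid$at_risk_years, NA_real_)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)

  out <- lapply(eval_points, function(t0) {
    w <- kf((t0 - grid$mid) / bandwidth)
    w[!ok] <- 0
    sw <- sum(w)
    if (sw <= 0) {
      return(data.table::data.table(time = t0, hazard = NA_real_,
                                    se_log = NA_real_, ci_low = NA_real_,
                                    ci_high = NA_real_, boundary = TRUE))
    }
    w <- w / sw
    h <- sum(w[ok] * rate[ok])
    v <- sum(w[ok]^2 * grid$events[ok] / grid$at_risk_years[ok]^2)
    se_log <- if (h > 0) sqrt(v) / h else NA_real_
    data.table::data.table(
      time = t0, hazard = h, se_log = se_log,
      ci_low = if (h > 0) h * exp(-z * se_log) else 0,
      ci_high = if (h > 0) h * exp(z * se_log) else 0,
      boundary = t0 < grid$edges[1] + bandwidth |
        t0 > grid$edges[length(grid$edges)] - bandwidth)
  })
  data.table::rbindlist(out)
}

#' Ratio of two smoothed hazard curves
#'
#' Pointwise ratio of two curves sharing the same evaluation points, with a
#' log-scale normal confidence interval combining both variances. Points
#' where the denominator hazard is zero (or either curve is undefined) are
#' masked.
#'
#' @param curve_a,curve_b outputs of [smooth_hazard()] on identical
#'   evaluation points.
#' @param conf_level confidence level.
#' @return `data.table` with `time`, `ratio`, `ci_low`, `ci_high`,
#'   `masked`, `boundary`.
#' @export
hazard_ratio_curve <- function(curve_a, curve_b, conf_level = 0.95) {
  if (nrow(curve_a) != nrow(curve_b) ||
      any(abs(curve_a$time - curve_b$time) > 1e-9)) {
    stop_config("curves must share evaluation points")
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  masked <- is.na(curve_a$hazard) | is.na(curve_b$hazard) |
    curve_b$hazard <= 0 | curve_a$hazard <= 0
  ratio <- ifelse(masked, NA_real_, curve_a$hazard / curve_b$hazard)
  se <- ifelse(masked, NA_real_,
               sqrt(curve_a$se_log^2 + curve_b$se_log^2))
  data.table::data.table(
    time = curve_a$time, ratio = ratio,
    ci_low = ratio * exp(-z * se), ci_high = ratio * exp(z * se),
    masked = masked,
    boundary = curve_a$boundary | curve_b$boundary)
}
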