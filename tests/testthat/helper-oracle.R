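# Independent brute-force oracles used across the exposure and person-time
# tests. These evaluate the exposure state pointwise from first principles
# (scanning all prescriptions at each sampled time), unlike the interval
# construction in the package.

# exposure state at arbitrary times, by scanning every prescription
oracle_state_at <- function(ep, times, grace = 30.4, recent_until = 182.4) {
  n <- nrow(ep)
  starts <- ep$start
  ends <- ep$start + ep$duration_days        # expected end of treatment
  wends <- ends + grace                      # end of the grace window
  state <- character(length(times))
  dose <- rep(NA_real_, length(times))
  cls <- rep(NA_character_, length(times))

  for (i in seq_along(times)) {
    t <- times[i]
    started <- starts <= t
    if (!any(started)) { state[i] <- NA_character_; next }
    if (any(started & t < wends)) {
      state[i] <- "current"
      active <- started & t < ends
      if (any(active)) {
        dose[i] <- sum(ep$ddd_mg[active])
        cls[i] <- class_label(ep$drug_class[active])
      } else {
        # grace gap: carry the dose active just before the latest expiry
        tau <- max(ends[ends <= t])
        carry <- starts < tau & tau <= ends
        dose[i] <- sum(ep$ddd_mg[carry])
        cls[i] <- class_label(ep$drug_class[carry])
      }
    } else {
      maxE <- max(ends[started])
      state[i] <- if (t < maxE + recent_until) "recent" else "past"
    }
  }
  list(state = state, dose = dose, cls = cls)
}

class_label <- function(classes) {
  ht <- any(classes == "typical"); ha <- any(classes == "atypical")
  if (ht && ha) "mixed" else if (ht) "typical" else "atypical"
}

# union of the current windows as a sorted interval list (simple merge loop)
oracle_current_union <- function(ep, grace = 30.4) {
  s <- ep$start
  e <- ep$start + ep$duration_days + grace
  o <- order(s)
  s <- s[o]; e <- e[o]
  us <- s[1]; ue <- e[1]
  out_s <- numeric(0); out_e <- numeric(0)
  if (length(s) > 1) {
    for (k in 2:length(s)) {
      if (s[k] <= ue) ue <- max(ue, e[k])
      else { out_s <- c(out_s, us); out_e <- c(out_e, ue); us <- s[k]; ue <- e[k] }
    }
  }
  out_s <- c(out_s, us); out_e <- c(out_e, ue)
  list(s = out_s, e = out_e)
}

# cumulative time spent in the current state before each time point
oracle_cum_current <- function(ep, times, grace = 30.4) {
  u <- oracle_current_union(ep, grace)
  vapply(times, function(t) {
    sum(pmax(pmin(u$e, t) - u$s, 0))
  }, numeric(1))
}

# look up the timeline interval covering each time point
timeline_lookup <- function(tl, times) {
  idx <- findInterval(times, tl$start)
  ok <- idx >= 1 & idx <= nrow(tl)
  res <- data.table::data.table(
    state = rep(NA_character_, length(times)),
    dose_band = rep(NA_character_, length(times)),
    cum_duration_band = rep(NA_character_, length(times)),
    drug_class = rep(NA_character_, length(times)))
  use <- which(ok)
  use <- use[times[use] < tl$end[idx[use]]]
  res$state[use] <- tl$state[idx[use]]
  res$dose_band[use] <- tl$dose_band[idx[use]]
  res$cum_duration_band[use] <- tl$cum_duration_band[idx[use]]
  res$drug_class[use] <- tl$drug_class[idx[use]]
  res
}

# random prescription sets with overlaps, grace-straddling gaps and mixed
# classes; integer dates and durations so sampled half-day time points
# never coincide with the fractional window boundaries
random_rx_set <- function(n_max = 20) {
  n <- sample.int(n_max, 1L)
  gaps <- sample(c(1:25, 30:45, 60:200), n, replace = TRUE)
  start <- cumsum(c(sample.int(30, 1L), gaps[-1]))
  data.table::data.table(
    patient_id = 1L,
    start = as.numeric(start),
    duration_days = as.numeric(sample(c(7, 14, 28, 56, 90), n,
                                      replace = TRUE)),
    ddd_mg = sample(c(50, 150, 250, 450), n, replace = TRUE),
    ddd_imputed = FALSE, duration_imputed = FALSE,
    drug_class = sample(c("typical", "atypical"), n, replace = TRUE)
  )[, expected_end := start + duration_days][]
}

# compare a built timeline against the pointwise oracle on a half-day grid
check_timeline_against_oracle <- function(ep, censor) {
  tl <- build_timeline(ep, censor)
  if (min(ep$start) >= censor) return(nrow(tl) == 0L)
  times <- seq(min(ep$start), censor - 0.25, by = 0.5)
  ora <- oracle_state_at(ep, times)
  got <- timeline_lookup(tl, times)
  ok_state <- identical(got$state, ora$state)
  cur <- !is.na(ora$state) & ora$state == "current"
  ok_dose <- all(got$dose_band[cur] == dose_band(ora$dose[cur]))
  ok_cls <- all(got$drug_class[cur] == ora$cls[cur])
  cum <- oracle_cum_current(ep, times[cur])
  ok_cum <- all(got$cum_duration_band[cur] == apcohort:::duration_band(cum))
  ok_state && ok_dose && ok_cls && ok_cum
}
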