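#' Build time-varying exposure timelines
#'
#' Converts standardised prescription episodes into a labelled exposure
#' timeline per patient. Current exposure runs from a prescription start to
#' one month (30.4 days) after the expected end of treatment; repeat
#' prescriptions issued within that grace window (inclusive boundary) are
#' stitched into the same continuous treatment window. Recent exposure runs
#' until six months (182.4 days) after the expected end of treatment, and
#' past exposure covers any later follow-up until censoring or the next
#' prescription, which reopens current exposure. Within current windows,
#' sub-segments carry the dose band of the active chlorpromazine-equivalent
#' daily dose (summed over concurrent prescriptions and carried through
#' grace gaps), the cumulative-treated-duration band, and the active drug
#' class (`mixed` when typical and atypical overlap).
#'
#' @param episodes output of [prepare_episodes()] (multiple patients).
#' @param censors `data.table(patient_id, censor_date)`.
#' @param grace grace period after the expected end of treatment (days).
#' @param recent_until end of recent exposure, measured from the expected
#'   end of treatment (days).
#' @param recent_from whether `recent_until` is measured from the expected
#'   end of treatment (default) or from the end of the current window.
#' @param duration_breaks cumulative-duration band edges in days.
#' @return `data.table` with columns `patient_id`, `start`, `end`, `state`,
#'   `dose_band`, `cum_duration_band`, `drug_class`; intervals are
#'   half-open, disjoint, ordered, and span first prescription to censoring.
#' @export
build_timelines <- function(episodes, censors,
                            grace = DAYS_PER_MONTH,
                            recent_until = DAYS_PER_HALF_YEAR,
                            recent_from = c("expected_end", "current_end"),
                            duration_breaks = c(1, 3) * DAYS_PER_YEAR) {
  recent_from <- match.arg(recent_from)
  ep <- merge(episodes, censors, by = "patient_id")
  ep <- ep[start < censor_date]
  if (nrow(ep) == 0L) return(empty_timeline())
  data.table::setorder(ep, patient_id, start)
  ep[, wend := expected_end + grace]
  ep[, cmax := cummax(wend), by = patient_id]
  ep[, newch := start > data.table::shift(cmax, fill = -Inf),
     by = patient_id]
  ep[, chain := cumsum(newch), by = patient_id]

  chains <- ep[, .(cs = min(start), maxE = max(expected_end),
                   has_typ = any(drug_class == "typical"),
                   has_aty = any(drug_class == "atypical"),
                   censor_date = censor_date[1L]),
               by = .(patient_id, chain)]
  chains[, ce := maxE + grace]
  if (recent_from == "expected_end") {
    chains[, re := maxE + recent_until]
  } else {
    chains[, re := ce + recent_until]
  }
  chains[, next_cs := data.table::shift(cs, type = "lead", fill = Inf),
         by = patient_id]
  chains[, chain_class := data.table::fifelse(
    has_typ & has_aty, "mixed",
    data.table::fifelse(has_typ, "typical", "atypical"))]
  chains[, cur_end := pmin(ce, censor_date, next_cs)]
  chains[, rec_end := pmin(re, censor_date, next_cs)]
  chains[, past_end := pmin(next_cs, censor_date)]
  chains[, cum0 := cumsum(data.table::shift(pmax(cur_end - cs, 0),
                                            fill = 0)), by = patient_id]

  # cumulative-duration thresholds crossed inside a current window
  cross <- list()
  for (theta in duration_breaks) {
    cc <- chains[cum0 < theta & cs + (theta - cum0) < cur_end,
                 .(patient_id, chain, t = cs + (theta - cum0))]
    cross[[as.character(theta)]] <- cc
  }
  cross <- data.table::rbindlist(cross)

  bp <- rbind(ep[, .(patient_id, chain, t = start)],
              ep[, .(patient_id, chain, t = expected_end)],
              chains[, .(patient_id, chain, t = cur_end)],
              cross)
  bp <- merge(bp, chains[, .(patient_id, chain, cs, cur_end)],
              by = c("patient_id", "chain"))
  bp <- unique(bp[t >= cs & t <= cur_end, .(patient_id, chain, t)])
  data.table::setorder(bp, patient_id, chain, t)
  bp[, e := data.table::shift(t, type = "lead"), by = .(patient_id, chain)]
  subs <- bp[!is.na(e) & e > t]
  subs[, mid := (t + e) / 2]

  act <- ep[subs, on = .(patient_id, start <= mid, expected_end > mid),
            .(dd = sum(ddd_mg), ht = any(drug_class == "typical"),
              ha = any(drug_class == "atypical")), by = .EACHI]
  subs[, `:=`(dd = act$dd, ht = act$ht, ha = act$ha)]
  subs[, c("ddd_active", "cls_active") := {
    has <- !is.na(dd) & dd > 0
    idx <- pmax(cummax(data.table::fifelse(has, seq_len(.N), 0L)), 1L)
    cls <- data.table::fifelse(
      ht[idx] & ha[idx], "mixed",
      data.table::fifelse(ht[idx], "typical", "atypical"))
    list(dd[idx], cls)
  }, by = .(patient_id, chain)]
  subs <- merge(subs, chains[, .(patient_id, chain, cs, cum0)],
                by = c("patient_id", "chain"), sort = FALSE)
  # evaluated at the segment midpoint: threshold crossings are segment
  # boundaries, and the midpoint is strictly inside its band
  subs[, cum_at := cum0 + (t + e) / 2 - cs]

  cur_ivl <- subs[, .(patient_id, start = t, end = e, state = "current",
                      dose_band = dose_band(ddd_active),
                      cum_duration_band = duration_band(cum_at,
                                                        duration_breaks),
                      drug_class = cls_active)]
  rec_ivl <- chains[rec_end > cur_end,
                    .(patient_id, start = cur_end, end = rec_end,
                      state = "recent", dose_band = NA_character_,
                      cum_duration_band = NA_character_,
                      drug_class = chain_class)]
  past_ivl <- chains[past_end > rec_end,
                     .(patient_id, start = rec_end, end = past_end,
                       state = "past", dose_band = NA_character_,
                       cum_duration_band = NA_character_,
                       drug_class = chain_class)]
  out <- rbind(cur_ivl, rec_ivl, past_ivl)
  data.table::setorder(out, patient_id, start)
  out[]
}

#' Exposure timeline for a single patient
#'
#' @param episodes episode rows for one patient (a `patient_id` column is
#'   added if absent).
#' @param censor_date end of follow-up.
#' @param ... passed to [build_timelines()].
#' @export
build_timeline <- function(episodes, censor_date, ...) {
  ep <- data.table::as.data.table(episodes)
  if (!"patient_id" %in% names(ep)) ep[, patient_id := 1L]
  stopifnot(data.table::uniqueN(ep$patient_id) <= 1L)
  censors <- data.table::data.table(patient_id = ep$patient_id[1],
                                    censor_date = censor_date)
  build_timelines(ep, censors, ...)
}

duration_band <- function(days, breaks = c(1, 3) * DAYS_PER_YEAR) {
  data.table::fifelse(days >= breaks[2], ">3y",
                      data.table::fifelse(days >= breaks[1], "1-3y", "<1y"))
}

empty_timeline <- function() {
  data.table::data.table(
    patient_id = integer(), start = numeric(), end = numeric(),
    state = character(), dose_band = character(),
    cum_duration_band = character(), drug_class = character())
}
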