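#' Generate outcome events, death-registry records and free-text notes
#'
#' Event times are drawn from piecewise-constant hazards: each generator
#' cause (`scd`, `cardiac_other`, `other_mortality`, `suicide`, plus the
#' nonfatal `chd` and `ventricular_arrhythmia` processes) has a baseline
#' rate, multiplied per patient by sex, psychiatric status and configured
#' confounder effects, multiplied by an attained-age step function over the
#' ten-year age bands, and multiplied during current antipsychotic exposure
#' by the planted rate ratios (including dose-band multipliers). Death
#' terminates follow-up. Deaths emit a death-certificate record with a
#' cause-appropriate ICD-10-like code; a configurable fraction also receive
#' a hospital episode ending shortly before death and a free-text note that
#' may or may not contain the sudden-death trigger strings (with a held-out
#' truth label for scoring).
#'
#' @param pts population from [generate_population()].
#' @param rx prescriptions from [generate_prescribing()] (with truth
#'   columns).
#' @param cfg the [sim_config()].
#' @return list with elements `patients` (death dates filled in), `events`
#'   (coded events across the three sources) and `freetext`.
#' @export
generate_outcomes <- function(pts, rx, cfg) {
  set.seed(stage_seed(cfg, "outcomes"))
  pts <- data.table::copy(pts)
  origin_year <- as.integer(format(cfg$origin_date, "%Y"))
  pts[, .birth_day := (birth_year - origin_year) * DAYS_PER_YEAR]

  segs <- hazard_segments(pts, rx)

  # patient-level log hazard multiplier shared by the death causes; the
  # age effect is time-varying and applied per segment below
  logm <- cfg$male_log_hr * (pts$sex == "M") +
    cfg$psych_log_hr * pts$.psych +
    confounder_shift(pts, cfg$confounder_effects, "outcome")
  mult <- data.table::data.table(patient_id = pts$patient_id,
                                 M = exp(logm),
                                 birth_day = pts$.birth_day)
  segs <- merge(segs, mult, by = "patient_id", sort = FALSE)

  # hazards rise with attained age as a step function over the ten-year
  # age bands: segments are split at band-crossing birthdays and carry the
  # multiplier of the band midpoint
  segs <- split_at_age_bands(segs, AGE_BAND_EDGES)
  segs[, age_attained := ((s + e) / 2 - birth_day) / DAYS_PER_YEAR]
  band_mid <- c(AGE_BAND_EDGES[1] - 5, AGE_BAND_EDGES + 5)
  segs[, M := M * exp(cfg$age_log_hr_per_decade *
                        (band_mid[findInterval(age_attained,
                                               AGE_BAND_EDGES) + 1L] -
                           60) / 10)]
  data.table::setorder(segs, patient_id, s)

  rr <- cfg$true_rr
  segs[, dose_mult := data.table::fifelse(
    current, cfg$dose_rr[dose_band_of(cpz)], 1)]
  exp_mult <- function(extra) {
    data.table::fifelse(segs$current,
                        rr$all_cause_mortality * extra * segs$dose_mult, 1)
  }
  bh <- cfg$baseline_hazards
  segs[, r_scd := bh$scd / DAYS_PER_YEAR * M * exp_mult(rr$cardiac_mortality * rr$scd)]
  segs[, r_card := bh$cardiac_other / DAYS_PER_YEAR * M * exp_mult(rr$cardiac_mortality)]
  segs[, r_other := bh$other_mortality / DAYS_PER_YEAR * M * exp_mult(1)]
  segs[, r_suic := bh$suicide / DAYS_PER_YEAR * M * exp_mult(1)]
  segs[, r_death := r_scd + r_card + r_other + r_suic]

  death <- draw_event_times(segs, "r_death")
  # cause sampled from the hazard mix active in the death segment
  if (nrow(death)) {
    u <- runif(nrow(death)) * death$rate
    death[, cause := data.table::fcase(
      u < r_scd, "scd",
      u < r_scd + r_card, "cardiac_other",
      u < r_scd + r_card + r_other, "other_mortality",
      default = "suicide")]
  } else {
    death[, cause := character(0)]
  }
  death[, t := floor(t)]
  death <- death[, .(patient_id, t, cause)]
  death <- merge(death, pts[, .(patient_id, .entry)], by = "patient_id")
  death <- death[t > .entry][, .(patient_id, t, cause)]

  pts[death, on = "patient_id", death_date := i.t]
  pts[!is.na(death_date) & !is.na(transfer_out) & transfer_out > death_date,
      transfer_out := NA_real_]
  pts[, .end_fu := pmin(.end, death_date, na.rm = TRUE)]

  # nonfatal first events, censored at death
  nonfatal <- list()
  for (oc in c("chd", "ventricular_arrhythmia")) {
    segs[, r_nf := bh[[oc]] / DAYS_PER_YEAR * M *
           data.table::fifelse(current, rr[[oc]] * dose_mult, 1)]
    ev <- draw_event_times(segs, "r_nf")
    ev[, t := floor(t)]
    ev <- merge(ev[, .(patient_id, t)],
                pts[, .(patient_id, .entry, .end_fu)], by = "patient_id")
    nonfatal[[oc]] <- ev[t < .end_fu & t > .entry, .(patient_id, t)]
  }

  events <- emit_coded_events(pts, death, nonfatal, cfg)
  freetext <- emit_freetext(pts, death, cfg)
  list(patients = pts, events = events, freetext = freetext)
}

# split hazard segments at age-band-crossing birthdays (segments must
# carry `s`, `e` and `birth_day`); other columns are preserved
split_at_age_bands <- function(segs, edges) {
  segs[, seg_id := .I]
  cr <- list()
  for (a in edges) {
    cross <- segs$birth_day + a * DAYS_PER_YEAR
    hit <- cross > segs$s & cross < segs$e
    if (any(hit)) {
      cr[[as.character(a)]] <- data.table::data.table(
        seg_id = segs$seg_id[hit], t = cross[hit])
    }
  }
  cr <- data.table::rbindlist(cr)
  if (nrow(cr) == 0L) {
    segs[, seg_id := NULL]
    return(segs)
  }
  bp <- rbind(segs[, .(seg_id, t = s)], cr, segs[, .(seg_id, t = e)])
  data.table::setorder(bp, seg_id, t)
  bp <- unique(bp)
  bp[, e2 := data.table::shift(t, type = "lead"), by = seg_id]
  sub <- bp[!is.na(e2) & e2 > t]
  attrs <- segs[, setdiff(names(segs), c("s", "e")), with = FALSE]
  out <- merge(sub, attrs, by = "seg_id", sort = FALSE)
  out[, `:=`(s = t, e = e2)]
  out[, c("t", "e2", "seg_id") := NULL]
  out[]
}

dose_band_of <- function(cpz) {
  data.table::fifelse(cpz >= 400, "high",
                      data.table::fifelse(cpz >= 200, "medium", "low"))
}

# truth exposure segments per patient: breakpoints at prescription starts,
# true expected ends and grace-window closures; `current` flags the
# grace-stitched treatment windows, `cpz` the active chlorpromazine-
# equivalent daily dose (carried through within-window gaps)
hazard_segments <- function(pts, rx) {
  base_cols <- pts[, .(patient_id, .entry, .end)]
  if (nrow(rx) == 0L) {
    out <- base_cols[, .(patient_id, s = .entry, e = .end,
                         current = FALSE, cpz = 0)]
    return(out)
  }
  rxw <- rx[, .(patient_id, s = date, e = date + .true_duration,
                cpz = .true_cpz)]
  rxw[, wend := e + DAYS_PER_MONTH]
  data.table::setorder(rxw, patient_id, s)
  rxw[, cmax := cummax(wend), by = patient_id]
  rxw[, newch := s > data.table::shift(cmax, fill = -Inf), by = patient_id]
  rxw[, chain := cumsum(newch), by = patient_id]
  chains <- rxw[, .(cs = min(s), ce = max(wend)),
                by = .(patient_id, chain)]

  treated_ids <- unique(rxw$patient_id)
  tb <- base_cols[patient_id %in% treated_ids]
  bp <- rbind(
    rxw[, .(patient_id, t = s)],
    rxw[, .(patient_id, t = e)],
    chains[, .(patient_id, t = ce)],
    tb[, .(patient_id, t = .entry)],
    tb[, .(patient_id, t = .end)]
  )
  bp <- merge(bp, tb, by = "patient_id", sort = FALSE)
  bp <- bp[t >= .entry & t <= .end]
  bp <- unique(bp[, .(patient_id, t)])
  data.table::setorder(bp, patient_id, t)
  bp[, e := data.table::shift(t, type = "lead"), by = patient_id]
  segs <- bp[!is.na(e) & e > t, .(patient_id, s = t, e)]
  segs[, mid := (s + e) / 2]

  cur <- chains[segs, on = .(patient_id, cs <= mid, ce > mid),
                which = TRUE, nomatch = NA]
  segs[, current := !is.na(cur)]
  act <- rxw[segs, on = .(patient_id, s <= mid, e > mid),
             .(cpz_sum = sum(cpz)), by = .EACHI]
  segs[, cpz_active := data.table::fifelse(is.na(act$cpz_sum), 0,
                                           act$cpz_sum)]
  segs[, cpz := {
    idx <- cummax(data.table::fifelse(cpz_active > 0, seq_len(.N), 0L))
    data.table::fifelse(idx > 0, cpz_active[pmax(idx, 1L)], 0)
  }, by = patient_id]
  segs[, mid := NULL]
  segs[, cpz_active := NULL]

  untreated <- base_cols[!patient_id %in% treated_ids,
                         .(patient_id, s = .entry, e = .end,
                           current = FALSE, cpz = 0)]
  out <- rbind(segs, untreated)
  data.table::setorder(out, patient_id, s)
  out[]
}

# inversion sampling of a piecewise-constant hazard: one exponential draw
# per patient located on the cumulative hazard of its segments. Patients
# with a single segment (the untreated majority) take a closed-form path.
draw_event_times <- function(segs, rate_col) {
  counts <- segs[, .N, by = patient_id]
  singles <- counts[N == 1L, patient_id]
  one <- segs[patient_id %in% singles]
  multi <- segs[!patient_id %in% singles]
  res <- list()
  if (nrow(one)) {
    r1 <- one[[rate_col]]
    E <- rexp(nrow(one))
    hit1 <- E < r1 * (one$e - one$s)
    if (any(hit1)) {
      o <- one[hit1]
      o[, rate := r1[hit1]]
      o[, t := s + E[hit1] / rate]
      res$one <- o
    }
  }
  if (nrow(multi)) {
    sg <- multi
    sg[, rate := sg[[rate_col]]]
    sg[, ch_end := cumsum(rate * (e - s)), by = patient_id]
    sg[, ch_start := ch_end - rate * (e - s)]
    ids <- unique(sg$patient_id)
    ed <- data.table::data.table(patient_id = ids, E = rexp(length(ids)))
    hit <- sg[ed, on = "patient_id", nomatch = NULL]
    hit <- hit[ch_start <= E & ch_end > E]
    hit[, t := s + (E - ch_start) / rate]
    hit[, c("ch_end", "ch_start", "E") := NULL]
    sg[, c("rate", "ch_end", "ch_start") := NULL]
    res$multi <- hit
  }
  data.table::rbindlist(res, use.names = TRUE, fill = TRUE)
}
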