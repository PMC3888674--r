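#' Run the full synthetic-record generator
#'
#' Convenience wrapper chaining [generate_population()],
#' [generate_prescribing()] and [generate_outcomes()].
#'
#' @param cfg a [sim_config()].
#' @return list with `patients`, `prescriptions`, `events`, `freetext` and
#'   the `config`.
#' @export
simulate_ehr <- function(cfg = sim_config()) {
  pts <- generate_population(cfg)
  rx <- generate_prescribing(pts, cfg)
  oc <- generate_outcomes(pts, rx, cfg)
  list(patients = oc$patients, prescriptions = rx, events = oc$events,
       freetext = oc$freetext, config = cfg)
}

#' Write the four record streams as delimited files
#'
#' Writes `patients.csv`, `prescriptions.csv`, `events.csv` and
#' `freetext.csv` (comma-separated, UTF-8, ISO dates) plus a
#' `manifest.json` echoing the seed and origin date. Internal bookkeeping
#' columns (dot-prefixed simulation truth) are dropped, except the
#' free-text `truth_label`, which is held out from the pipeline but kept
#' for test scoring.
#'
#' @param sim result of [simulate_ehr()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ehr <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  origin <- sim$config$origin_date
  date_cols <- list(
    patients = c("registration_date", "data_start", "transfer_out",
                 "death_date", "dx_schizophrenia", "dx_bipolar",
                 "dx_major_depression", "dx_dementia"),
    prescriptions = "date",
    events = c("date", "admission_date", "discharge_date"),
    freetext = "date")
  for (nm in c("patients", "prescriptions", "events", "freetext")) {
    tab <- data.table::copy(sim[[nm]])
    drop <- grep("^\\.", names(tab), value = TRUE)
    if (length(drop)) tab[, (drop) := NULL]
    for (dc in intersect(date_cols[[nm]], names(tab))) {
      data.table::set(tab, j = dc, value = offset_to_date(tab[[dc]], origin))
    }
    data.table::fwrite(tab, file.path(dir, paste0(nm, ".csv")))
  }
  manifest <- list(seed = sim$config$seed,
                   origin_date = format(origin),
                   horizon_years = sim$config$horizon_years,
                   n_patients = nrow(sim$patients),
                   rows = lapply(sim[c("patients", "prescriptions",
                                       "events", "freetext")], nrow))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read the four record streams back from disk
#'
#' Inverse of [write_ehr()]: parses the delimited files, converts ISO dates
#' back to day offsets from the manifest's origin date, and restores the
#' derived entry/end bookkeeping columns.
#'
#' @param dir directory written by [write_ehr()].
#' @return list with `patients`, `prescriptions`, `events`, `freetext`,
#'   `origin_date`.
#' @export
read_ehr <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  origin <- as.Date(man$origin_date)
  H <- man$horizon_years * DAYS_PER_YEAR
  rd <- function(nm, dc) {
    f <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(f)) stop_config("missing input table: %s", f)
    tab <- data.table::fread(f)
    for (col in intersect(dc, names(tab))) {
      data.table::set(tab, j = col,
                      value = date_to_offset(tab[[col]], origin))
    }
    tab
  }
  patients <- rd("patients", c("registration_date", "data_start",
                               "transfer_out", "death_date",
                               "dx_schizophrenia", "dx_bipolar",
                               "dx_major_depression", "dx_dementia"))
  patients[, .entry := pmax(registration_date, data_start)]
  patients[, .end := pmin(data.table::fifelse(is.na(transfer_out), H,
                                              transfer_out), H)]
  patients[, .end_fu := pmin(.end, death_date, na.rm = TRUE)]
  list(patients = patients,
       prescriptions = rd("prescriptions", "date"),
       events = rd("events", c("date", "admission_date", "discharge_date")),
       freetext = rd("freetext", "date"),
       origin_date = origin)
}
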