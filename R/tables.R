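ICD_CHAPTERS <- c(
  A = "A00-B99 infectious and parasitic", B = "A00-B99 infectious and parasitic",
  C = "C00-D89 neoplasms and blood", D = "C00-D89 neoplasms and blood",
  E = "E00-E90 endocrine and metabolic", F = "F00-F99 mental and behavioural",
  G = "G00-G99 nervous system", H = "H00-H95 eye and ear",
  I = "I00-I99 circulatory system", J = "J00-J99 respiratory system",
  K = "K00-K93 digestive system", L = "L00-L99 skin",
  M = "M00-M99 musculoskeletal", N = "N00-N99 genitourinary",
  O = "O00-O99 pregnancy", P = "P00-P96 perinatal",
  Q = "Q00-Q99 congenital", R = "R00-R99 symptoms and signs",
  S = "V01-Y98 external causes", T = "V01-Y98 external causes",
  V = "V01-Y98 external causes", W = "V01-Y98 external causes",
  X = "V01-Y98 external causes", Y = "V01-Y98 external causes")

icd_chapter <- function(codes) {
  unname(ICD_CHAPTERS[substr(codes, 1, 1)])
}

#' Causes of death by ICD-10 chapter among current users
#'
#' Tabulates deaths occurring during current antipsychotic exposure by the
#' ICD-10 chapter of the death-certificate cause, split by the first
#' prescribed drug class, with incidence rates per 1000 person-years of
#' current exposure.
#'
#' @param users user cohort table (with `first_class`).
#' @param timelines exposure timelines ([build_timelines()]).
#' @param events coded events (death certificates).
#' @param patients patients table.
#' @return `data.table` with chapter, class, events, percentage and rate.
#' @export
cause_of_death_table <- function(users, timelines, events, patients) {
  certs <- events[source == "death_certificate",
                  .(patient_id, cause = code)]
  u <- merge(users, patients[, .(patient_id, death_date)],
             by = "patient_id")
  u <- merge(u, certs, by = "patient_id")
  u <- u[!is.na(death_date) & death_date > index_date &
           death_date <= censor_date]
  cur <- timelines[state == "current"]
  hit <- cur[u, on = .(patient_id, start <= death_date, end > death_date),
             nomatch = NULL, .(patient_id = i.patient_id)]
  u <- u[patient_id %in% hit$patient_id]
  u[, chapter := icd_chapter(cause)]

  py <- merge(cur, users[, .(patient_id, first_class, index_date,
                             censor_date)], by = "patient_id")
  py <- py[, .(py = sum(pmax(pmin(end, censor_date) -
                               pmax(start, index_date), 0)) / DAYS_PER_YEAR),
           by = first_class]
  tab <- u[, .(events = .N), by = .(first_class, chapter)]
  tab <- merge(tab, py, by = "first_class")
  tab[, pct := 100 * events / sum(events), by = first_class]
  tab[, rate_per_1000py := 1000 * events / py]
  data.table::setorder(tab, first_class, chapter)
  tab[]
}
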