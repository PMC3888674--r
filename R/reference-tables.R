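#' Antipsychotic drug reference table
#'
#' Screened oral antipsychotics with their class (typical/atypical), an
#' approximate chlorpromazine-equivalence factor and the tablet strengths the
#' simulator draws from. The equivalence factor is milligrams of
#' chlorpromazine judged therapeutically equivalent to one milligram of the
#' drug, assembled from published consensus equivalence tables; it is a
#' package default and can be overridden by supplying a modified table to
#' [compute_ddd()].
#'
#' @return a `data.table` with columns `drug_name`, `drug_class`,
#'   `cpz_factor` (mg chlorpromazine per mg drug) and `strengths`
#'   (list-column of tablet strengths in mg).
#' @export
antipsychotic_drugs <- function() {
  atypical <- list(
    # name            cpz_factor  strengths (mg/tablet)
    amisulpride   = list(1,     c(50, 100, 200, 400)),
    aripiprazole  = list(13.3,  c(5, 10, 15, 30)),
    clozapine     = list(2,     c(25, 100, 200)),
    olanzapine    = list(20,    c(2.5, 5, 10, 15, 20)),
    paliperidone  = list(66.7,  c(3, 6, 9)),
    quetiapine    = list(1.33,  c(25, 100, 200, 300)),
    risperidone   = list(50,    c(0.5, 1, 2, 3, 4)),
    sertindole    = list(25,    c(4, 12, 16, 20)),
    zotepine      = list(2,     c(25, 50, 100))
  )
  typical <- list(
    benperidol      = list(100,  c(0.25)),
    chlorpromazine  = list(1,    c(25, 50, 100)),
    chlorprothixene = list(1,    c(15, 50, 100)),
    droperidol      = list(25,   c(10)),
    flupentixol     = list(50,   c(0.5, 1, 3)),
    fluphenazine    = list(50,   c(1, 2.5, 5)),
    haloperidol     = list(50,   c(0.5, 1.5, 5, 10)),
    levomepromazine = list(1,    c(25, 100)),
    loxapine        = list(10,   c(10, 25, 50)),
    oxypertine      = list(2.5,  c(10, 40)),
    pericyazine     = list(10,   c(2.5, 10)),
    perphenazine    = list(12.5, c(2, 4, 8)),
    pimozide        = list(50,   c(2, 4)),
    promazine       = list(1,    c(25, 50)),
    remoxipride     = list(0.67, c(100, 150, 300)),
    sulpiride       = list(0.5,  c(200, 400)),
    thioridazine    = list(1,    c(10, 25, 50, 100)),
    trifluoperazine = list(20,   c(1, 5)),
    trifluperidol   = list(200,  c(0.5, 1)),
    zuclopenthixol  = list(4,    c(2, 10, 25))
  )
  build <- function(lst, cls) {
    data.table::data.table(
      drug_name = names(lst),
      drug_class = cls,
      cpz_factor = vapply(lst, function(x) x[[1]], numeric(1)),
      strengths = lapply(lst, function(x) x[[2]])
    )
  }
  out <- rbind(build(typical, "typical"), build(atypical, "atypical"))
  data.table::setkey(out, drug_name)
  out[]
}

#' Load packaged outcome, exclusion and free-text code sets
#'
#' Reads the plain-text code-set configuration shipped with the package (or a
#' user-supplied file in the same format). ICD-10 entries are matched
#' hierarchically (an entry matches any code it prefixes once dots are
#' removed); primary-care stand-in codes are matched exactly.
#'
#' @param path optional path to an alternative YAML code-set file.
#' @return a nested list with elements `icd10`, `primary_care`,
#'   `exclusion_conditions` and `free_text`; primary-care equivalents of each
#'   ICD-10 outcome set are added under `primary_care` as `RC_` codes.
#' @export
load_code_sets <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "code_sets.yaml", package = "apcohort")
  }
  if (!file.exists(path)) stop_config("code-set file not found: %s", path)
  cs <- yaml::read_yaml(path)
  # mirror each ICD-10 outcome set into the Read-like namespace
  for (nm in setdiff(names(cs$icd10), "suicide")) {
    rc <- paste0("RC_", gsub(".", "", cs$icd10[[nm]], fixed = TRUE))
    cs$primary_care[[nm]] <- unique(c(cs$primary_care[[nm]], rc))
  }
  cs$free_text$triggers <- lapply(cs$free_text$triggers, as.character)
  cs
}

#' Hierarchical ICD-10 code matching
#'
#' @param codes character vector of recorded codes.
#' @param set character vector of code-set entries; an entry matches any
#'   recorded code that it prefixes after dots are removed.
#' @return logical vector along `codes`.
#' @export
icd_match <- function(codes, set) {
  if (length(codes) == 0L) return(logical(0))
  cc <- gsub(".", "", codes, fixed = TRUE)
  ss <- unique(gsub(".", "", set, fixed = TRUE))
  out <- rep(FALSE, length(cc))
  for (s in ss) out <- out | startsWith(cc, s)
  out
}

# prefix matching for the compact primary-care stand-in codes, mirroring
# the hierarchical ICD-10 semantics they are derived from
read_match <- function(codes, set) {
  out <- rep(FALSE, length(codes))
  for (s in unique(set)) out <- out | startsWith(codes, s)
  out
}

# convert an ICD-10 entry to its primary-care stand-in
as_read_code <- function(icd) paste0("RC_", gsub(".", "", icd, fixed = TRUE))
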