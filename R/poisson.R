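#' Model specification for adjusted rate-ratio fitting
#'
#' Encodes the covariate-selection rules: age, sex and the treatment
#' contrast are forced into every model; candidate confounders enter a
#' backward-elimination pass, with the candidate pool truncated so the
#' number of non-forced parameters never exceeds one per
#' `events_per_parameter` outcome events; covariates with Wald P >= 0.10
#' are eliminated and only those with P < 0.05 are retained. Candidates are
#' considered in the (alphabetically sorted, hence deterministic) order of
#' `candidates`.
#'
#' @param candidates candidate covariate columns.
#' @param forced covariates always kept (besides the exposure contrast).
#' @param events_per_parameter events-per-parameter budget rule.
#' @param p_enter retention threshold for the final model.
#' @param p_remove elimination threshold during backward steps.
#' @export
model_spec <- function(candidates = c("alcohol_drug_abuse", "bmi_band",
                                      "deprivation", "diabetes",
                                      "prior_psych_admission", "smoking",
                                      "suicide_attempt"),
                       forced = c("age_band", "sex"),
                       events_per_parameter = 5,
                       p_enter = 0.05, p_remove = 0.10) {
  stopifnot(events_per_parameter > 0, p_enter <= p_remove)
  list(candidates = sort(candidates), forced = forced,
       events_per_parameter = events_per_parameter,
       p_enter = p_enter, p_remove = p_remove)
}

# aggregated-cell Poisson fit with log person-time offset; cells with zero
# person-time are dropped. Factors are releveled so `reference` is the
# exposure baseline.
fit_cells <- function(cells, exposure, reference, terms) {
  df <- as.data.frame(cells[person_years > 0])
  df[[exposure]] <- stats::relevel(factor(df[[exposure]]), ref = reference)
  # constant columns carry no contrast and are dropped from the fit
  terms <- terms[vapply(terms, function(tm) length(unique(df[[tm]])) > 1L,
                        logical(1))]
  for (tm in terms) {
    if (is.character(df[[tm]])) df[[tm]] <- factor(df[[tm]])
  }
  rhs <- paste(c(exposure, terms), collapse = " + ")
  fm <- stats::as.formula(paste("events ~", rhs))
  stats::glm(fm, family = stats::poisson(),
             offset = log(df$person_years), data = df,
             control = stats::glm.control(epsilon = 1e-10, maxit = 100))
}

# joint Wald test for all coefficients belonging to one covariate column
block_wald_p <- function(fit, col) {
  cf <- stats::coef(fit)
  idx <- which(startsWith(names(cf), col) & !is.na(cf))
  if (!length(idx)) return(1)
  V <- stats::vcov(fit)[idx, idx, drop = FALSE]
  b <- cf[idx]
  W <- tryCatch(drop(t(b) %*% solve(V, b)), error = function(e) NA_real_)
  if (!is.finite(W)) return(1)
  stats::pchisq(W, df = length(idx), lower.tail = FALSE)
}

# non-reference parameter count a covariate would add to the model
n_params <- function(cells, col) {
  v <- cells[[col]]
  if (is.numeric(v)) 1L else max(data.table::uniqueN(v) - 1L, 0L)
}

#' Backward covariate selection under an events-per-parameter budget
#'
#' Truncates the candidate pool so non-forced parameters stay within
#' `events / events_per_parameter`, then backward-eliminates candidates
#' with joint Wald P >= `p_remove` and finally drops any with
#' P >= `p_enter`. Deterministic given the candidate order.
#'
#' @param cells person-time cells containing the candidate columns.
#' @param spec a [model_spec()].
#' @param exposure exposure column name.
#' @param reference reference exposure level.
#' @return character vector of retained candidate covariates.
#' @export
select_covariates <- function(cells, spec = model_spec(),
                              exposure = "exposure",
                              reference) {
  total_events <- sum(cells$events)
  budget <- floor(total_events / spec$events_per_parameter)
  pool <- character(0)
  used <- 0L
  for (cand in spec$candidates) {
    if (!cand %in% names(cells)) next
    k <- n_params(cells, cand)
    if (k == 0L) next
    if (used + k <= budget) {
      pool <- c(pool, cand)
      used <- used + k
    }
  }
  if (!length(pool)) return(character(0))

  repeat {
    fit <- fit_cells(cells, exposure, reference, c(spec$forced, pool))
    pv <- vapply(pool, function(cc) block_wald_p(fit, cc), numeric(1))
    worst <- which.max(pv)
    if (pv[worst] >= spec$p_remove) {
      pool <- pool[-worst]
      if (!length(pool)) return(character(0))
    } else break
  }
  # final retention rule: keep only candidates significant at p_enter
  repeat {
    fit <- fit_cells(cells, exposure, reference, c(spec$forced, pool))
    pv <- vapply(pool, function(cc) block_wald_p(fit, cc), numeric(1))
    worst <- which.max(pv)
    if (length(pool) && pv[worst] >= spec$p_enter) {
      pool <- pool[-worst]
      if (!length(pool)) return(character(0))
    } else break
  }
  pool
}

#' Poisson rate-ratio estimation from person-time cells
#'
#' Log-linear event-count model with a log person-years offset, fitted by
#' iteratively reweighted least squares (`stats::glm`, deviance tolerance
#' 1e-10, up to 100 iterations). `adjustment = "age_sex"` includes only the
#' forced covariates; `adjustment = "full"` first runs
#' [select_covariates()] on the cells. Comparisons where the exposed or
#' reference group has no events are flagged not-calculable (`NC`) instead
#' of fitted.
#'
#' @param cells person-time cells from [accumulate_person_time()].
#' @param exposure exposure column.
#' @param reference reference level of `exposure`.
#' @param adjustment `"crude"`, `"age_sex"` or `"full"`.
#' @param spec a [model_spec()] (used for `"full"`).
#' @param conf_level confidence level for the Wald interval.
#' @return `data.table` with one row per non-reference exposure level:
#'   rate ratio, confidence limits, Wald P, events and person-years per
#'   arm, retained covariates, and an `nc` flag.
#' @export
fit_rate_ratio <- function(cells, exposure = "exposure", reference,
                           adjustment = c("age_sex", "crude", "full"),
                           spec = model_spec(), conf_level = 0.95) {
  adjustment <- match.arg(adjustment)
  lv <- unique(cells[[exposure]])
  stopifnot(reference %in% lv)
  arm <- cells[, .(events = sum(events),
                   person_years = sum(person_years)),
               by = c(exposure)]
  data.table::setnames(arm, exposure, "level")
  ref_arm <- arm[level == reference]
  comp <- arm[level != reference]

  terms <- switch(adjustment,
                  crude = character(0),
                  age_sex = c("age_band", "sex"),
                  full = c("age_band", "sex"))
  retained <- character(0)
  if (adjustment == "full") {
    retained <- select_covariates(cells, spec, exposure, reference)
    terms <- c(terms, retained)
  }
  terms <- intersect(terms, names(cells))

  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  rows <- lapply(comp$level, function(lev) {
    nc_row <- data.table::data.table(
      comparison = lev, reference = reference, adjustment = adjustment,
      rr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
      p_value = NA_real_,
      events_exposed = comp[level == lev, events],
      py_exposed = comp[level == lev, person_years],
      events_reference = ref_arm$events,
      py_reference = ref_arm$person_years,
      covariates_retained = paste(retained, collapse = ";"),
      nc = TRUE)
    if (comp[level == lev, events] == 0L || ref_arm$events == 0L ||
        comp[level == lev, person_years] <= 0 ||
        ref_arm$person_years <= 0) {
      return(nc_row)
    }
    keep_rows <- cells[[exposure]] %in% c(reference, lev)
    sub <- cells[keep_rows]
    fit <- fit_cells(sub, exposure, reference, terms)
    cf <- stats::coef(fit)
    nm <- paste0(exposure, lev)
    if (!nm %in% names(cf) || is.na(cf[nm])) return(nc_row)
    b <- cf[nm]
    se <- sqrt(stats::vcov(fit)[nm, nm])
    nc_row[, `:=`(rr = exp(b), ci_low = exp(b - z * se),
                  ci_high = exp(b + z * se),
                  p_value = 2 * stats::pnorm(-abs(b / se)), nc = FALSE)]
    nc_row
  })
  data.table::rbindlist(rows)
}

#' Stratified rate ratios
#'
#' Re-estimates the exposure contrast within strata of a cell column. For
#' user-side strata (dose band, drug class, cumulative-duration band) the
#' reference person-time has no stratum label and is shared across strata;
#' for common strata (age band) both arms are subset.
#'
#' @param cells person-time cells containing `by`.
#' @param by stratifying column.
#' @param exposure,reference,adjustment,spec as in [fit_rate_ratio()].
#' @param shared_reference `TRUE` when only exposed cells carry the
#'   stratum label.
#' @return `data.table` of estimates with a `stratum` column.
#' @export
stratified_rr <- function(cells, by, exposure = "exposure", reference,
                          adjustment = "age_sex", spec = model_spec(),
                          shared_reference = TRUE) {
  levs <- sort(unique(stats::na.omit(cells[[by]])))
  out <- lapply(levs, function(lv) {
    keep_rows <- if (shared_reference) {
      cells[[exposure]] == reference |
        (!is.na(cells[[by]]) & cells[[by]] == lv)
    } else {
      !is.na(cells[[by]]) & cells[[by]] == lv
    }
    sub <- cells[keep_rows]
    est <- fit_rate_ratio(sub, exposure, reference, adjustment, spec)
    est[, stratum := lv]
    est
  })
  data.table::rbindlist(out)
}
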