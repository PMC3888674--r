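# Calendar conventions used throughout the package. Dates are handled
# internally as (possibly fractional) day offsets from a run origin date, and
# every interval is half-open [start, end). One calendar month is 30.4 days,
# six months 182.4 days, one year 365.25 days, three weeks 21 days.
DAYS_PER_MONTH <- 30.4
DAYS_PER_HALF_YEAR <- 182.4
DAYS_PER_YEAR <- 365.25
FREE_TEXT_WINDOW_DAYS <- 21

# default ten-year age bands shared by the simulator's attained-age hazard
# step function and the models' age adjustment
AGE_BAND_EDGES <- c(30, 40, 50, 60, 70, 80)

#' Convert day offsets to calendar dates
#'
#' @param days numeric day offsets (may be fractional; floored).
#' @param origin origin date (`Date` or ISO string).
#' @return a `Date` vector.
#' @export
offset_to_date <- function(days, origin) {
  as.Date(origin) + floor(days)
}

#' Convert calendar dates to day offsets
#'
#' @param dates `Date` vector (or ISO strings).
#' @param origin origin date (`Date` or ISO string).
#' @return numeric day offsets from `origin`.
#' @export
date_to_offset <- function(dates, origin) {
  as.numeric(as.Date(dates) - as.Date(origin))
}

# year (calendar) of a day offset, for e.g. the free-text start-year rule
offset_year <- function(days, origin) {
  as.integer(format(offset_to_date(days, origin), "%Y"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}
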