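#' 8-day compositing calendar
#'
#' Daily layers are aggregated into 46 fixed periods per year, each labelled
#' by the zero-padded Julian day on which it starts (001, 009, ..., 361).
#' All periods span 8 days except the last, which runs from day 361 to the
#' end of the year (5 days in a common year, 6 in a leap year).
#'
#' @param year integer calendar year.
#' @return `period_starts()` returns the 46 starting Julian days;
#'   `days_in_year()` the number of days in `year`; `period_of_day()` the
#'   starting day of the period containing a Julian day; `period_length()`
#'   the number of days a period covers in a given year.
#' @name composite-calendar
NULL

#' @rdname composite-calendar
#' @export
period_starts <- function() seq.int(1L, 361L, by = 8L)

#' @rdname composite-calendar
#' @export
days_in_year <- function(year) {
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  ifelse(leap, 366L, 365L)
}

#' @rdname composite-calendar
#' @param jday Julian day of year (1-366).
#' @export
period_of_day <- function(jday) {
  stopifnot(all(jday >= 1), all(jday <= 366))
  ifelse(jday >= 361L, 361L, ((as.integer(jday) - 1L) %/% 8L) * 8L + 1L)
}

#' @rdname composite-calendar
#' @param start starting Julian day of a period (one of `period_starts()`).
#' @export
period_length <- function(start, year) {
  stopifnot(all(start %in% period_starts()))
  ifelse(start < 361L, 8L, days_in_year(year) - 360L)
}

#' @rdname composite-calendar
#' @export
period_label <- function(start) sprintf("%03d", as.integer(start))

#' Julian day of a calendar date
#' @param date a `Date` vector.
#' @return integer day-of-year (1 = Jan 1).
#' @export
julian_day <- function(date) as.integer(format(as.Date(date), "%j"))

#' Day overlap of an 8-day period with each calendar month
#'
#' Used for day-weighted monthly aggregation: a period starting on Julian
#' day 25 of a common year contributes 7 days to January and 1 to February.
#'
#' @param start starting Julian day of the period.
#' @param year calendar year.
#' @return named integer vector, names "1".."12", days of the period falling
#'   in each month (months with zero overlap omitted).
#' @export
period_month_days <- function(start, year) {
  len <- period_length(start, year)
  days <- as.Date(sprintf("%d-01-01", year)) + (start - 1L) + seq_len(len) - 1L
  tab <- table(as.integer(format(days, "%m")))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' @rdname composite-calendar
#' @param month month number 1-12.
#' @export
days_in_month <- function(month, year) {
  base <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  n <- base[month]
  n[month == 2L] <- n[month == 2L] + (days_in_year(year) - 365L)
  n
}
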