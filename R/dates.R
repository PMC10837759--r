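#' Calendar-month arithmetic with day clamping
#'
#' All recall intervals and validity periods in the platform are expressed in
#' whole calendar months, so month arithmetic is calendar-based with the day
#' of month clamped to the target month's length (Jan 31 + 1 month gives
#' Feb 28, or Feb 29 in a leap year). Time of day is never represented:
#' every clinical rule operates at day granularity.
#'
#' @param date a `Date` (or string coercible to one)
#' @param months integer number of months to add (may be negative)
#' @return a `Date`
#' @examples
#' add_months(as.Date("2023-01-31"), 1)  # 2023-02-28
#' add_months(as.Date("2020-01-31"), 1)  # 2020-02-29
#' @export
add_months <- function(date, months) {
  date <- as.Date(date)
  stopifnot(length(months) == 1L, is.finite(months))
  months <- as.integer(months)
  lt <- as.POSIXlt(date)
  y <- lt$year + 1900L
  m <- lt$mon + 1L + months
  d <- lt$mday
  y <- y + (m - 1L) %/% 12L
  m <- (m - 1L) %% 12L + 1L
  d <- pmin(d, days_in_month(y, m))
  as.Date(sprintf("%04d-%02d-%02d", y, m, d))
}

days_in_month <- function(year, month) {
  dm <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  leap <- (year %% 4L == 0L & year %% 100L != 0L) | year %% 400L == 0L
  ifelse(month == 2L & leap, 29L, dm[month])
}

#' Completed calendar months between two dates
#'
#' Counts whole months from `from` to `to`: the count increments on the
#' monthly anniversary day itself (with day clamping at month ends), matching
#' how parameter validity and recall intervals are aged.
#'
#' @param from,to `Date`s with `from <= to`
#' @return integer count of completed months
#' @export
months_between <- function(from, to) {
  from <- as.Date(from); to <- as.Date(to)
  if (from > to) stop("`from` must not be after `to`")
  lf <- as.POSIXlt(from); lt <- as.POSIXlt(to)
  n <- (lt$year - lf$year) * 12L + (lt$mon - lf$mon)
  # back off one month if the anniversary day has not yet been reached
  if (n > 0L && add_months(from, n) > to) n <- n - 1L
  as.integer(n)
}

#' Completed age in years
#'
#' Standard completed-years age; the age increments on the birthday itself.
#' Used by every age-based eligibility predicate.
#'
#' @param birth_date date of birth
#' @param as_of reference date (must not precede `birth_date`)
#' @return integer age in completed years
#' @examples
#' age_at(as.Date("1980-06-15"), as.Date("2020-06-14"))  # 39
#' age_at(as.Date("1980-06-15"), as.Date("2020-06-15"))  # 40
#' @export
age_at <- function(birth_date, as_of) {
  birth_date <- as.Date(birth_date); as_of <- as.Date(as_of)
  if (birth_date > as_of) stop("birth_date is after as_of")
  months_between(birth_date, as_of) %/% 12L
}

as_iso_date <- function(x) format(as.Date(x), "%Y-%m-%d")
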