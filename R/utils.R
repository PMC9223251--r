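# Date arithmetic shared by the person-year engine and the simulator.
# All exposure is measured in days / 365.25 so that slice cuts are exact.

DAYS_PER_YEAR <- 365.25

`%||%` <- function(a, b) if (is.null(a)) b else a

is_leap <- function(y) (y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0

# leap days in years strictly before y
nleap_before <- function(y) {
  y1 <- y - 1
  floor(y1 / 4) - floor(y1 / 100) + floor(y1 / 400)
}

# cumulative days before each month in a non-leap year
DAYS_BEFORE_MONTH <- c(0L, 31L, 59L, 90L, 120L, 151L, 181L, 212L, 243L,
                       273L, 304L, 334L)

#' First day of a calendar year
#' @keywords internal
jan1 <- function(year) {
  days <- (year - 1970) * 365L + (nleap_before(year) - nleap_before(1970))
  structure(as.numeric(days), class = "Date")
}

#' Calendar year of a date
#' @keywords internal
year_of <- function(date) data.table::year(date)

#' Anniversary of a date in a given calendar year
#'
#' Returns the month/day of `origin` placed in calendar year `year`.
#' Feb 29 anniversaries fall on Mar 1 in non-leap years, the usual
#' demographic convention for birthday-based Lexis cuts.
#'
#' @param origin Date vector (recycled against `year`).
#' @param year integer vector of calendar years.
#' @return Date vector.
#' @keywords internal
anniversary <- function(origin, year) {
  n <- max(length(origin), length(year))
  origin <- rep_len(origin, n)
  year <- rep_len(year, n)
  m <- data.table::month(origin)
  d <- data.table::mday(origin)
  offset <- DAYS_BEFORE_MONTH[m] + (d - 1L) + (m > 2L) * is_leap(year)
  jan1(year) + offset
}

#' Shift a date by whole years (anniversary convention)
#' @param date Date vector.
#' @param n integer number of years (scalar or vector).
#' @return Date vector.
#' @keywords internal
add_years <- function(date, n) {
  anniversary(date, year_of(date) + n)
}

#' Completed age in years at a date
#'
#' @param date Date vector.
#' @param birth Date vector of birth dates.
#' @return integer vector of completed years.
#' @keywords internal
age_at <- function(date, birth) {
  n <- max(length(date), length(birth))
  date <- rep_len(date, n)
  birth <- rep_len(birth, n)
  y <- year_of(date) - year_of(birth)
  bday <- anniversary(birth, year_of(date))
  as.integer(y - (date < bday))
}

# qx <-> hazard transforms. The terminal open age group carries qx = 1;
# clamp so the constant-hazard conversion stays finite.
QX_MAX <- 1 - 1e-10

qx_to_mu <- function(qx) -log1p(-pmin(qx, QX_MAX))
mu_to_qx <- function(mu) -expm1(-mu)

# log cumulative-hazard transform used for interpolation
qx_to_z <- function(qx) log(qx_to_mu(qx))
z_to_qx <- function(z) mu_to_qx(exp(z))

clamp01 <- function(x, lo = 1e-12, hi = 1) pmin(pmax(x, lo), hi)
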