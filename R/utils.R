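# Internal date helpers.
#
# All durations are counted in whole days and converted to years by /365.25;
# ages are completed years, incrementing on the birthday itself (a Feb 29
# birthday falls on Mar 1 in non-leap years).

DAYS_PER_YEAR <- 365.25

# Vectorized integer civil-calendar arithmetic (proleptic Gregorian; days
# since 1970-01-01). Avoids POSIXlt round trips on large vectors.
civil_from_days <- function(z) {
  z <- as.integer(z) + 719468L
  era <- z %/% 146097L
  doe <- z - era * 146097L
  yoe <- (doe - doe %/% 1460L + doe %/% 36524L - doe %/% 146096L) %/% 365L
  y <- yoe + era * 400L
  doy <- doe - (365L * yoe + yoe %/% 4L - yoe %/% 100L)
  mp <- (5L * doy + 2L) %/% 153L
  d <- doy - (153L * mp + 2L) %/% 5L + 1L
  m <- mp + ifelse(mp < 10L, 3L, -9L)
  list(year = y + (m <= 2L), month = m, day = d)
}

days_from_civil <- function(y, m, d) {
  y <- as.integer(y) - (m <= 2L)
  era <- y %/% 400L
  yoe <- y - era * 400L
  doy <- (153L * (m + ifelse(m > 2L, -3L, 9L)) + 2L) %/% 5L + d - 1L
  doe <- yoe * 365L + yoe %/% 4L - yoe %/% 100L + doy
  era * 146097L + doe - 719468L
}

#' Completed age in years at a date
#'
#' Age increments on the birthday itself; a Feb 29 birthday increments on
#' Mar 1 in non-leap years.
#' @param birth,date `Date` vectors (recycled).
#' @return Integer vector of completed years.
#' @noRd
age_completed <- function(birth, date) {
  b <- civil_from_days(as.integer(birth))
  d <- civil_from_days(as.integer(date))
  before <- (d$month < b$month) | (d$month == b$month & d$day < b$day)
  as.integer(d$year - b$year - before)
}

# Date at which a person born on `birth` turns `years` old (Feb 29 births
# roll to Mar 1 in non-leap years, matching age_completed()).
anniversary_date <- function(birth, years) {
  b <- civil_from_days(as.integer(birth))
  as.Date(days_from_civil(b$year + years, b$month, b$day),
          origin = "1970-01-01")
}

days_to_years <- function(days) as.numeric(days) / DAYS_PER_YEAR

# Scalar-argument validation helpers ------------------------------------------

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s].", name, lower, upper))
  }
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be TRUE or FALSE.", name))
  }
  invisible(x)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing mandatory column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
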