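#' Parse FAERS partial dates
#'
#' FAERS date fields are numeric strings of 4 (year), 6 (year-month) or
#' 8 (year-month-day) digits. Anything else parses as missing.
#'
#' @param x Character vector of raw date strings.
#' @return A tibble with one row per input: `year`, `month`, `day`
#'   (integer, `NA` where absent) and `precision`
#'   (`"year"`, `"month"`, `"day"` or `NA` for unparseable input).
#' @examples
#' parse_partial_date(c("20230415", "202304", "2023", "bad", NA))
#' @export
parse_partial_date <- function(x) {
  x <- stringr::str_trim(as.character(x))
  x[!stringr::str_detect(x, "^[0-9]{4}([0-9]{2}([0-9]{2})?)?$") | is.na(x)] <- NA_character_
  n <- stringr::str_length(x)
  year <- as.integer(stringr::str_sub(x, 1L, 4L))
  month <- ifelse(n >= 6L, as.integer(stringr::str_sub(x, 5L, 6L)), NA_integer_)
  day <- ifelse(n == 8L, as.integer(stringr::str_sub(x, 7L, 8L)), NA_integer_)
  # reject impossible calendar components rather than guessing
  bad_month <- !is.na(month) & (month < 1L | month > 12L)
  bad_day <- !is.na(day) & (day < 1L | day > 31L)
  month[bad_month] <- NA_integer_
  day[bad_month | bad_day] <- NA_integer_
  precision <- dplyr::case_when(
    is.na(year) ~ NA_character_,
    !is.na(day) ~ "day",
    !is.na(month) ~ "month",
    TRUE ~ "year"
  )
  tibble::tibble(year = year, month = month, day = day, precision = precision)
}

#' Convert partial dates to Date, requiring day precision
#'
#' Date arithmetic (onset intervals) is only defined for day-precise values;
#' coarser dates yield `NA` rather than an imputed mid-month convention.
#'
#' @param x Character vector of raw FAERS date strings.
#' @return A `Date` vector, `NA` unless the input is a valid 8-digit date.
#' @export
partial_date_as_date <- function(x) {
  pd <- parse_partial_date(x)
  out <- rep(as.Date(NA), length(x))
  ok <- !is.na(pd$precision) & pd$precision == "day"
  if (any(ok)) {
    out[ok] <- as.Date(
      sprintf("%04d-%02d-%02d", pd$year[ok], pd$month[ok], pd$day[ok]),
      format = "%Y-%m-%d"
    )
  }
  out
}

#' Extract the year from a partial date
#'
#' @param x Character vector of raw FAERS date strings.
#' @return Integer year, `NA` where unparseable.
#' @export
partial_date_year <- function(x) {
  parse_partial_date(x)$year
}

#' Numeric sort key for FDA receipt dates
#'
#' Pads year- and month-precision dates with zeros so that a coarse date
#' sorts before any day-precise date of the same year — a deterministic
#' total order for the deduplication rule.
#'
#' @param x Character vector of raw FAERS date strings.
#' @return Numeric key (`NA` for unparseable dates).
#' @keywords internal
partial_date_key <- function(x) {
  pd <- parse_partial_date(x)
  ifelse(
    is.na(pd$year), NA_real_,
    pd$year * 10000 +
      dplyr::coalesce(pd$month, 0L) * 100 +
      dplyr::coalesce(pd$day, 0L)
  )
}
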