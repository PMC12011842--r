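#' Convert a reported age to years
#'
#' FAERS ages carry a unit code: DEC (decades), YR (years), MON (months),
#' WK (weeks), DY (days), HR (hours). Conversions use the mean calendar
#' factors 52.18 weeks, 365.25 days and 8,766 hours per year. Results
#' outside the plausible human range of 0 to 122 years become missing, as
#' do unknown unit codes (with a warning).
#'
#' @param value Numeric age values.
#' @param unit_code Character unit codes, recycled against `value`.
#' @return Numeric age in years, `NA` where unconvertible.
#' @examples
#' convert_age(c(62, 24, 6), c("YR", "MON", "DEC"))
#' @export
convert_age <- function(value, unit_code) {
  factors <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.18,
               DY = 1 / 365.25, HR = 1 / 8766)
  unit_code <- toupper(as.character(unit_code))
  unknown <- !is.na(unit_code) & !(unit_code %in% names(factors))
  if (any(unknown)) {
    warning(sprintf(
      "unknown age unit code(s) treated as missing: %s",
      paste(unique(unit_code[unknown]), collapse = ", ")
    ), call. = FALSE)
  }
  years <- as.numeric(value) * unname(factors[unit_code])
  years[is.na(years) | years < 0 | years > 122] <- NA_real_
  years
}

#' Time from therapy start to event onset
#'
#' Days between the earliest day-precise therapy start date among a case's
#' primary-suspect drugs and its event date. Either date lacking day
#' precision yields missing; negative intervals (start after event) and
#' intervals over 3,653 days (10 years, almost certainly a data error in a
#' spontaneous report) are also treated as missing.
#'
#' @param cases Deduplicated case tibble with `primaryid` and `event_dt`.
#' @param drug Standardized DRUG tibble with `primaryid`, `drug_seq`,
#'   `role_cod`.
#' @param ther THER tibble with `primaryid`, `dsg_drug_seq`, `start_dt`.
#' @param role_filter Drug roles whose therapy episodes count (default
#'   primary suspect only).
#' @param max_days Upper plausibility bound in days.
#' @return A tibble `primaryid`, `onset_days` (integer, `NA` where
#'   undefined), one row per case in `cases`.
#' @export
case_onset_days <- function(cases, drug, ther, role_filter = "PS",
                            max_days = 3653) {
  starts <- drug |>
    dplyr::filter(.data$role_cod %in% role_filter) |>
    dplyr::inner_join(
      ther,
      by = c("primaryid", "drug_seq" = "dsg_drug_seq"),
      relationship = "many-to-many"
    ) |>
    dplyr::mutate(start_date = partial_date_as_date(.data$start_dt)) |>
    dplyr::filter(!is.na(.data$start_date)) |>
    dplyr::group_by(.data$primaryid) |>
    # sort()[1] rather than min(): silent on dplyr's empty type probe
    dplyr::summarise(start_date = sort(.data$start_date)[1], .groups = "drop")

  cases |>
    dplyr::select("primaryid", "event_dt") |>
    dplyr::left_join(starts, by = "primaryid") |>
    dplyr::mutate(
      event_date = partial_date_as_date(.data$event_dt),
      onset_days = as.integer(.data$event_date - .data$start_date),
      onset_days = dplyr::if_else(
        !is.na(.data$onset_days) &
          (.data$onset_days < 0L | .data$onset_days > max_days),
        NA_integer_, .data$onset_days
      )
    ) |>
    dplyr::select("primaryid", "onset_days")
}

#' Round a percentage half-up to two decimals
#'
#' Matches the presentation convention of published characteristic tables:
#' `count / total * 100`, rounded half-up (so 0.005 rounds to 0.01) to two
#' decimal places.
#'
#' @param count,total Numeric, vectorized.
#' @return Numeric percentage on the 0-100 scale.
#' @examples
#' percent_of(23188, 32187) # 72.04
#' @export
percent_of <- function(count, total) {
  out <- floor(count / total * 100 * 100 + 0.5) / 100
  out[rep_len(!(total > 0), length(out))] <- NA_real_
  out
}

#' Read a country-to-region mapping
#'
#' @param path CSV with columns `country`, `region`. Defaults to the
#'   packaged table of ISO-style country codes to continents.
#' @return A tibble `country`, `region`.
#' @export
read_region_map <- function(path = system.file("extdata", "country_regions.csv",
                                               package = "faerslahl")) {
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
}

occupation_labels <- c(
  MD = "Physician", PH = "Pharmacist", OT = "Other health-professional",
  CN = "Consumer", LW = "Lawyer"
)

outcome_labels <- c(
  LT = "Life-Threatening",
  HO = "Hospitalization - Initial or Prolonged",
  DS = "Disability",
  DE = "Death",
  CA = "Congenital Anomaly",
  RI = "Required Intervention to Prevent Permanent Impairment/Damage",
  OT = "Other serious medical events"
)

#' Assemble one summary row per event case
#'
#' Joins demographics, outcomes and onset times into the per-case table
#' that feeds [summarize_cases()] and [yearly_counts()]. The reporting
#' country is taken from the occurrence-country field with
#' reporter-country fallback by default (`country_field = "occurrence"`),
#' or the reverse (`"reporter"`); regions come from the country-to-region
#' table with unknown countries mapped to "Not Specified". A case is
#' serious iff it has at least one outcome record.
#'
#' @param cases Deduplicated event-case tibble (DEMO columns).
#' @param outc OUTC tibble.
#' @param drug,ther Standardized DRUG and THER tibbles (for onset times);
#'   pass `NULL` to skip onset computation.
#' @param region_map Tibble from [read_region_map()].
#' @param country_field `"occurrence"` or `"reporter"`.
#' @return A tibble with one row per case: `caseid`, `primaryid`,
#'   `age_years`, `sex`, `occupation`, `country`, `region`, `outcomes`
#'   (list of codes), `serious`, `report_year`, `onset_days`.
#' @export
build_case_summaries <- function(cases, outc, drug = NULL, ther = NULL,
                                 region_map = read_region_map(),
                                 country_field = c("occurrence", "reporter")) {
  country_field <- match.arg(country_field)
  # derived columns are rebuilt here; drop clashing input columns
  cases <- dplyr::select(
    cases, -dplyr::any_of(c("outcomes", "region", "occupation", "country"))
  )
  outcome_sets <- outc |>
    dplyr::semi_join(cases, by = "primaryid") |>
    dplyr::filter(.data$outc_cod %in% names(outcome_labels)) |>
    dplyr::group_by(.data$primaryid) |>
    dplyr::summarise(outcomes = list(unique(.data$outc_cod)), .groups = "drop")

  country_vec <- if (country_field == "occurrence") {
    dplyr::coalesce(cases$occr_country, cases$reporter_country)
  } else {
    dplyr::coalesce(cases$reporter_country, cases$occr_country)
  }

  out <- cases |>
    dplyr::mutate(
      age_years = convert_age(.data$age, .data$age_cod),
      sex = dplyr::if_else(.data$sex %in% c("F", "M"), .data$sex, NA_character_),
      occupation = occupation_labels[.data$occp_cod],
      country = .env$country_vec,
      report_year = partial_date_year(.data$fda_dt)
    ) |>
    dplyr::left_join(region_map, by = "country") |>
    dplyr::left_join(outcome_sets, by = "primaryid") |>
    dplyr::mutate(
      region = dplyr::coalesce(.data$region, "Not Specified"),
      outcomes = purrr::map(.data$outcomes, ~ .x %||% character(0)),
      serious = lengths(.data$outcomes) > 0L
    )

  if (!is.null(drug) && !is.null(ther)) {
    out <- dplyr::left_join(
      out, case_onset_days(cases, drug, ther),
      by = "primaryid"
    )
  } else {
    out$onset_days <- NA_integer_
  }
  dplyr::select(
    out, "caseid", "primaryid", "age_years", "sex", "occupation",
    "country", "region", "outcomes", "serious", "report_year", "onset_days"
  )
}

count_section <- function(section, values, total, levels = NULL,
                          na_label = "Not Specified") {
  values <- dplyr::coalesce(values, na_label)
  tab <- tibble::tibble(category = values) |>
    dplyr::count(.data$category, name = "count")
  if (!is.null(levels)) {
    tab <- tab |>
      dplyr::full_join(tibble::tibble(category = levels), by = "category") |>
      dplyr::mutate(count = dplyr::coalesce(.data$count, 0L)) |>
      dplyr::arrange(match(.data$category, levels))
  } else {
    tab <- dplyr::arrange(tab, dplyr::desc(.data$count), .data$category)
  }
  tab |>
    dplyr::mutate(
      section = section,
      percent = percent_of(.data$count, total),
      .before = 1
    )
}

#' Characteristic table of the event-case population
#'
#' Produces a tidy version of the classic published characteristics table:
#' gender, age (median and quartiles, with missing count), reporter
#' occupation, top reporting countries, region, outcomes (non-exclusive:
#' a case can have several, so outcome percentages may sum over 100) and
#' seriousness. Percentages are count/total on the 0-100 scale, rounded
#' half-up to two decimals.
#'
#' @param summaries Per-case tibble from [build_case_summaries()].
#' @param top_countries Number of individually listed countries (default
#'   5); the rest are pooled into "Others".
#' @return A tibble with columns `section`, `category`, `count`,
#'   `percent`. Continuous rows (age, onset) appear in sections
#'   `"Age"`/`"Onset"` with `category` of `"Median"`, `"Q1"`, `"Q3"`,
#'   `"N"`, `"Missing"` and the statistic in `count`.
#' @export
summarize_cases <- function(summaries, top_countries = 5) {
  total <- nrow(summaries)
  if (total == 0L) {
    return(tibble::tibble(
      section = character(0), category = character(0),
      count = numeric(0), percent = numeric(0)
    ))
  }
  sex_labels <- c(F = "Female", M = "Male")
  gender <- count_section(
    "Gender", unname(sex_labels[summaries$sex]), total,
    levels = c("Female", "Male", "Not Specified")
  )
  occupation <- count_section(
    "Occupation of the reporter", summaries$occupation, total,
    levels = c(unname(occupation_labels), "Not Specified")
  )

  known <- summaries$country[!is.na(summaries$country)]
  top <- names(sort(table(known), decreasing = TRUE))
  top <- top[seq_len(min(top_countries, length(top)))]
  country_vals <- dplyr::case_when(
    is.na(summaries$country) ~ "Not Specified",
    summaries$country %in% top ~ summaries$country,
    TRUE ~ "Others"
  )
  country <- count_section(
    "Country of the reporter", country_vals, total,
    levels = c(top, "Others", "Not Specified")
  )
  region <- count_section("Region of the reporter", summaries$region, total)

  outcome_counts <- purrr::map_int(
    names(outcome_labels),
    function(code) sum(purrr::map_lgl(summaries$outcomes, ~ code %in% .x))
  )
  outcomes <- tibble::tibble(
    section = "Outcome",
    category = unname(outcome_labels),
    count = outcome_counts,
    percent = percent_of(outcome_counts, total)
  )
  seriousness <- count_section(
    "Seriousness",
    dplyr::if_else(summaries$serious, "Serious", "Non-Serious"), total,
    levels = c("Serious", "Non-Serious")
  )

  numeric_section <- function(section, x) {
    known <- x[!is.na(x)]
    q <- if (length(known) > 0) {
      stats::quantile(known, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
    } else {
      rep(NA_real_, 3)
    }
    tibble::tibble(
      section = section,
      category = c("Median", "Q1", "Q3", "N", "Missing"),
      count = c(q[1], q[2], q[3], length(known), sum(is.na(x))),
      percent = NA_real_
    )
  }

  dplyr::bind_rows(
    gender,
    numeric_section("Age", summaries$age_years),
    occupation, country, region, outcomes, seriousness,
    numeric_section("Onset", summaries$onset_days)
  )
}

#' Event cases per FDA receipt year
#'
#' @param summaries Per-case tibble from [build_case_summaries()].
#' @param span Optional integer vector of years to cover; defaults to the
#'   observed range. Years without cases are reported as zero.
#' @return A tibble `year`, `n_cases`.
#' @export
yearly_counts <- function(summaries, span = NULL) {
  years <- summaries$report_year[!is.na(summaries$report_year)]
  if (is.null(span)) {
    if (length(years) == 0L) {
      return(tibble::tibble(year = integer(0), n_cases = integer(0)))
    }
    span <- seq(min(years), max(years))
  }
  tibble::tibble(year = as.integer(years)) |>
    dplyr::count(.data$year, name = "n_cases") |>
    dplyr::full_join(tibble::tibble(year = as.integer(span)), by = "year") |>
    dplyr::mutate(n_cases = dplyr::coalesce(.data$n_cases, 0L)) |>
    dplyr::arrange(.data$year) |>
    dplyr::filter(.data$year %in% span)
}

#' Bin onset times for presentation
#'
#' Default bins follow the published presentation: 30 days or less, 31-60,
#' 61-90, and over 90 days.
#'
#' @param summaries Per-case tibble from [build_case_summaries()].
#' @param breaks Upper bin edges in days (the last bin is open-ended).
#' @return A tibble `bin`, `n_cases` (missing onsets excluded).
#' @export
onset_bins <- function(summaries, breaks = c(30, 60, 90)) {
  x <- summaries$onset_days[!is.na(summaries$onset_days)]
  labels <- c(
    sprintf("<=%d", breaks[1]),
    sprintf("%d-%d", breaks[-length(breaks)] + 1, breaks[-1]),
    sprintf(">%d", breaks[length(breaks)])
  )
  idx <- findInterval(x, breaks, left.open = TRUE) + 1L
  tibble::tibble(bin = factor(labels[idx], levels = labels)) |>
    dplyr::count(.data$bin, name = "n_cases", .drop = FALSE)
}
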