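test_that("age conversion applies unit factors and plausibility bounds", {
  expect_equal(convert_age(62, "YR"), 62)
  expect_equal(convert_age(24, "MON"), 2)
  expect_equal(convert_age(6, "DEC"), 60)
  expect_equal(convert_age(730.5, "DY"), 2)
  expect_true(is.na(convert_age(200, "YR"))) # outside [0, 122]
  expect_true(is.na(convert_age(-5, "YR")))
  expect_true(is.na(convert_age(NA, "YR")))
  expect_warning(out <- convert_age(5, "FORTNIGHT"), "unknown age unit")
  expect_true(is.na(out))
})

onset_fixture <- function(event_dt, start_dt) {
  cases <- tibble::tibble(primaryid = "1", caseid = "c1", event_dt = event_dt)
  drug <- tibble::tibble(
    primaryid = "1", drug_seq = 1L, role_cod = "PS",
    drugname = "x", ingredient_key = "x", mapped = TRUE
  )
  ther <- tibble::tibble(
    primaryid = "1", dsg_drug_seq = 1L, start_dt = start_dt, end_dt = NA_character_
  )
  case_onset_days(cases, drug, ther)$onset_days
}

test_that("onset time is event date minus earliest day-precise therapy start", {
  expect_equal(onset_fixture("20200126", "20200101"), 25L)
  expect_true(is.na(onset_fixture("202001", "20200101"))) # month precision
  expect_true(is.na(onset_fixture("20200101", "20200126"))) # start after event
  expect_true(is.na(onset_fixture("20200101", NA))) # no therapy record
  expect_true(is.na(onset_fixture("20300101", "20190101"))) # > 10 years
  # earliest of several episodes wins
  cases <- tibble::tibble(primaryid = "1", caseid = "c1", event_dt = "20200201")
  drug <- tibble::tibble(
    primaryid = c("1", "1"), drug_seq = c(1L, 2L), role_cod = c("PS", "PS"),
    drugname = c("x", "y"), ingredient_key = c("x", "y"), mapped = TRUE
  )
  ther <- tibble::tibble(
    primaryid = c("1", "1"), dsg_drug_seq = c(1L, 2L),
    start_dt = c("20200120", "20200101"), end_dt = NA_character_
  )
  expect_equal(case_onset_days(cases, drug, ther)$onset_days, 31L)
})

test_that("percentages round half-up to two decimals", {
  expect_equal(percent_of(23188, 32187), 72.04)
  expect_equal(percent_of(7003, 32187), 21.76)
  expect_equal(percent_of(1, 8), 12.5)
  expect_equal(percent_of(5, 1000), 0.5)
  expect_equal(percent_of(15, 2000), 0.75)
  expect_equal(percent_of(0, 10), 0)
})

summaries_fixture <- function(n = 300, seed = 21) {
  cfg <- synth_config(
    n_reports = n, n_quarters = 2, duplicate_rate = 0, deletion_rate = 0,
    background_event_prob = 0.5, seed = seed
  )
  cases <- synth_cases(cfg)
  cases$primaryid <- paste0(cases$caseid, "1")
  outc <- tidyr::unnest(
    tibble::tibble(primaryid = cases$primaryid, outc_cod = cases$outcomes),
    cols = "outc_cod"
  )
  demo <- dplyr::rename(cases, occr_country = country)
  demo$reporter_country <- demo$occr_country
  build_case_summaries(demo, outc)
}

test_that("characteristic table partitions are internally consistent", {
  s <- summaries_fixture()
  tab <- summarize_cases(s)
  total <- nrow(s)
  gender <- tab[tab$section == "Gender", ]
  expect_equal(sum(gender$count), total)
  region <- tab[tab$section == "Region of the reporter", ]
  expect_equal(sum(region$count), total)
  country <- tab[tab$section == "Country of the reporter", ]
  expect_equal(sum(country$count), total)
  serious <- tab[tab$section == "Seriousness", ]
  expect_equal(sum(serious$count), total)
  # percentages re-parse to count/total within rounding
  counted <- tab[!is.na(tab$percent), ]
  expect_true(all(abs(counted$percent - counted$count / total * 100) <= 0.005 + 1e-9))
  # age bookkeeping: N + Missing = total
  age <- tab[tab$section == "Age", ]
  expect_equal(
    age$count[age$category == "N"] + age$count[age$category == "Missing"],
    total
  )
})

test_that("empty case sets give an empty characteristic table", {
  s <- summaries_fixture()[0, ]
  expect_equal(nrow(summarize_cases(s)), 0L)
})

test_that("yearly counts bin by receipt year and include zero years", {
  s <- tibble::tibble(report_year = c(2020L, 2020L, 2020L, 2022L))
  yc <- yearly_counts(s)
  expect_equal(yc$year, 2020:2022)
  expect_equal(yc$n_cases, c(3L, 0L, 1L))
  expect_equal(nrow(yearly_counts(s[0, ])), 0L)
  # explicit span pads outside the observed range
  yc2 <- yearly_counts(s, span = 2019:2023)
  expect_equal(yc2$n_cases, c(0L, 3L, 0L, 1L, 0L))
})

test_that("synthetic uniform receipt dates give near-uniform yearly counts", {
  cfg <- synth_config(
    n_reports = 2000, n_quarters = 8, duplicate_rate = 0, deletion_rate = 0,
    start_date = as.Date("2021-01-01"), seed = 13
  )
  cases <- synth_cases(cfg)
  years <- partial_date_year(cases$fda_dt)
  counts <- table(years)
  expect_equal(names(counts), c("2021", "2022"))
  # two full years, multinomial error around 1000 each
  expect_true(all(abs(counts - 1000) < 4 * sqrt(2000 * 0.5 * 0.5)))
})

test_that("onset bins follow the published cut points", {
  s <- tibble::tibble(onset_days = c(0L, 30L, 31L, 60L, 61L, 90L, 91L, NA))
  b <- onset_bins(s)
  expect_equal(as.character(b$bin), c("<=30", "31-60", "61-90", ">90"))
  expect_equal(b$n_cases, c(2L, 2L, 2L, 1L))
})
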