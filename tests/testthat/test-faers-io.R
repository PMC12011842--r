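test_that("partial dates parse at year, month and day precision", {
  pd <- parse_partial_date(c("20230415", "202304", "2023", "garbage", "20231350", NA))
  expect_equal(pd$precision, c("day", "month", "year", NA, "year", NA))
  expect_equal(pd$year, c(2023L, 2023L, 2023L, NA, 2023L, NA))
  expect_equal(pd$day, c(15L, NA, NA, NA, NA, NA))
  expect_equal(
    partial_date_as_date(c("20230415", "202304")),
    as.Date(c("2023-04-15", NA))
  )
  # coarse dates sort before any day-precise date of the same year
  expect_lt(
    faerslahl:::partial_date_key("2023"),
    faerslahl:::partial_date_key("20230101")
  )
})

test_that("header line is not a record and field order comes from the header", {
  dir <- withr::local_tempdir()
  writeLines(
    c(
      "caseid$fda_dt$primaryid", # shuffled column order
      "1001$20230110$10011",
      "1002$20230215$10021"
    ),
    file.path(dir, "DEMO_2023Q1.txt")
  )
  for (tb in c("DRUG", "REAC", "THER", "OUTC")) {
    writeLines("primaryid", file.path(dir, sprintf("%s_2023Q1.txt", tb)))
  }
  # DRUG/REAC/THER/OUTC headers above lack mandatory columns
  writeLines(c("primaryid$drug_seq$role_cod$drugname"), file.path(dir, "DRUG_2023Q1.txt"))
  writeLines(c("primaryid$pt"), file.path(dir, "REAC_2023Q1.txt"))
  writeLines(c("primaryid$dsg_drug_seq"), file.path(dir, "THER_2023Q1.txt"))
  writeLines(c("primaryid$outc_cod"), file.path(dir, "OUTC_2023Q1.txt"))
  q <- read_faers_quarter(dir, "2023Q1")
  expect_equal(nrow(q$demo), 2L)
  expect_equal(q$demo$primaryid, c("10011", "10021"))
  expect_equal(q$demo$caseid, c("1001", "1002"))
})

test_that("malformed lines are skipped and counted, never silently dropped", {
  dir <- withr::local_tempdir()
  bundle <- tiny_bundle()
  write_faers_quarter(bundle, dir, "2023Q1")
  # corrupt one DEMO line with an extra delimiter
  path <- file.path(dir, "DEMO_2023Q1.txt")
  lines <- readLines(path)
  lines[3] <- paste0(lines[3], "$EXTRA")
  writeLines(lines, path)
  q <- read_faers_quarter(dir, "2023Q1")
  n_data_lines <- length(lines) - 1L
  expect_equal(nrow(q$demo) + unname(q$skipped["demo"]), n_data_lines)
  expect_equal(unname(q$skipped["demo"]), 1L)
})

test_that("missing files and missing mandatory columns raise named errors", {
  dir <- withr::local_tempdir()
  write_faers_quarter(tiny_bundle(), dir, "2023Q1")
  file.remove(file.path(dir, "REAC_2023Q1.txt"))
  expect_error(read_faers_quarter(dir, "2023Q1"), "REAC_2023Q1")

  dir2 <- withr::local_tempdir()
  write_faers_quarter(tiny_bundle(), dir2, "2023Q1")
  demo_path <- file.path(dir2, "DEMO_2023Q1.txt")
  lines <- readLines(demo_path)
  lines[1] <- sub("fda_dt", "renamed_beyond_recognition", lines[1])
  writeLines(lines, demo_path)
  expect_error(read_faers_quarter(dir2, "2023Q1"), "fda_dt")
})

test_that("write then parse is the identity on well-formed bundles", {
  set.seed(11)
  for (i in 1:5) {
    bundle <- random_bundle(n = 15)
    dir <- withr::local_tempdir()
    write_faers_quarter(bundle, dir, "2023Q2")
    q <- read_faers_quarter(dir, "2023Q2")
    for (tb in c("demo", "drug", "reac", "ther", "outc")) {
      got <- tibble::as_tibble(q[[tb]])
      attr(got, "n_skipped") <- NULL
      expect_equal(as.data.frame(got), as.data.frame(bundle[[tb]]),
        ignore_attr = TRUE
      )
    }
    expect_true(all(q$skipped == 0L))
  }
})

test_that("non-ASCII drug names survive the round trip byte-exactly", {
  bundle <- tiny_bundle()
  bundle$drug$drugname[1] <- "Caféine forte"
  dir <- withr::local_tempdir()
  write_faers_quarter(bundle, dir, "2023Q1")
  q <- read_faers_quarter(dir, "2023Q1")
  expect_identical(q$drug$drugname[1], "Caféine forte")
})

test_that("empty bundles write header-only files", {
  bundle <- purrr::map(tiny_bundle(), ~ .x[0, ])
  dir <- withr::local_tempdir()
  paths <- write_faers_quarter(bundle, dir, "2023Q1")
  expect_equal(length(readLines(paths[["demo"]])), 1L)
  q <- read_faers_quarter(dir, "2023Q1")
  expect_equal(nrow(q$demo), 0L)
})

test_that("deleted-case lists follow set semantics and absence is legal", {
  dir <- withr::local_tempdir()
  expect_identical(read_deleted_cases(dir, "2018Q4"), character(0))
  writeLines(c(" 1001 ", "1002", "1001", ""), file.path(dir, "DELETED_2019Q1.txt"))
  ids <- read_deleted_cases(dir, "2019Q1")
  expect_setequal(ids, c("1001", "1002"))
  expect_length(ids, 2L)
})
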