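test_that("invalid configs are rejected with the offending field named", {
  expect_error(synth_config(n_reports = 0), "n_reports")
  expect_error(synth_config(duplicate_rate = 1), "duplicate_rate")
  expect_error(synth_config(background_event_prob = 1.4), "background_event_prob")
  expect_error(
    synth_config(drugs_per_report_dist = c("1" = 0.6, "2" = 0.6)),
    "drugs_per_report_dist"
  )
  expect_error(
    synth_config(planted_odds_ratios = c(-1)),
    "planted_odds_ratios"
  )
  vocab <- default_drug_vocabulary()
  vocab$prob <- vocab$prob * 2
  expect_error(synth_config(drug_vocabulary = vocab), "drug_vocabulary")
})

test_that("same config and seed give byte-identical files and manifest", {
  cfg <- synth_config(n_reports = 300, n_quarters = 2, seed = 9)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- generate_faers_package(cfg, d1)
  m2 <- generate_faers_package(cfg, d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_equal(m1$ground_truth, m2$ground_truth)
})

test_that("without duplication each case is one DEMO row", {
  cfg <- synth_config(
    n_reports = 100, n_quarters = 2, duplicate_rate = 0, deletion_rate = 0,
    seed = 4
  )
  dir <- withr::local_tempdir()
  man <- generate_faers_package(cfg, dir)
  demo_rows <- sum(purrr::map_int(man$quarters, function(q) {
    nrow(read_faers_quarter(dir, q)$demo)
  }))
  expect_equal(demo_rows, 100L)
})

test_that("null planted odds ratios give balanced event proportions", {
  cfg <- synth_config(
    n_reports = 8000, planted_odds_ratios = numeric(0),
    duplicate_rate = 0, deletion_rate = 0, seed = 6
  )
  gt <- synth_ground_truth(cfg)
  p_drug <- gt$a / (gt$a + gt$b)
  p_rest <- gt$c / (gt$c + gt$d)
  # binomial error: each key's proportion near the background rate
  se <- sqrt(0.05 * 0.95 / (gt$a + gt$b))
  expect_true(all(abs(p_drug - p_rest) < 4 * se))
})

test_that("fast ground-truth path agrees with the written manifest", {
  cfg <- synth_config(n_reports = 500, n_quarters = 2, seed = 12)
  dir <- withr::local_tempdir()
  man <- generate_faers_package(cfg, dir)
  expect_equal(synth_ground_truth(cfg), man$ground_truth)
})

test_that("ground-truth signal sets honour the criteria", {
  cfg <- synth_config(n_reports = 20000, seed = 2) # planted linezolid OR = 10
  gt <- synth_ground_truth(cfg)
  man <- list(ground_truth = gt)
  keys <- ground_truth_signals(man)
  expect_true("linezolid" %in% keys)
  # a key with fewer than 3 event reports is never returned
  low <- gt$ingredient_key[gt$a < 3]
  expect_length(intersect(low, keys), 0L)
  # strict criteria knock out weak signals
  strict <- signal_criteria(min_a = 1e6)
  expect_length(ground_truth_signals(man, strict), 0L)
})

test_that("duplicate versions never alter drugs or reactions", {
  cfg <- synth_config(n_reports = 400, n_quarters = 2, duplicate_rate = 0.5,
                      deletion_rate = 0, seed = 15)
  dir <- withr::local_tempdir()
  man <- generate_faers_package(cfg, dir)
  qs <- purrr::map(man$quarters, ~ read_faers_quarter(dir, .x))
  demo <- dplyr::bind_rows(purrr::map(qs, "demo"))
  drug <- dplyr::bind_rows(purrr::map(qs, "drug"))
  dup_cases <- demo$caseid[duplicated(demo$caseid)]
  expect_gt(length(dup_cases), 0L)
  for (cid in dup_cases[1:10]) {
    pids <- demo$primaryid[demo$caseid == cid]
    sets <- purrr::map(pids, function(p) {
      d <- drug[drug$primaryid == p, c("drug_seq", "role_cod", "drugname")]
      d[order(d$drug_seq), ]
    })
    for (s in sets[-1]) expect_equal(s, sets[[1]], ignore_attr = TRUE)
  }
})

test_that("deletions require a 2019-era quarter to carry the list", {
  expect_error(
    generate_faers_package(
      synth_config(
        n_reports = 50, start_date = as.Date("2017-01-01"), n_quarters = 2,
        deletion_rate = 0.1, seed = 1
      ),
      withr::local_tempdir()
    ),
    "deletion_rate"
  )
})
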