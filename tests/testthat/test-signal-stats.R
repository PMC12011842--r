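test_that("disproportionality statistics match direct arithmetic", {
  rs <- ror_stats(20, 80, 10, 90)
  expect_equal(rs$ror, 2.25)
  expect_equal(prr_stats(20, 80, 10, 90), 2)
  expect_equal(chi_square_stat(20, 80, 10, 90),
               200 * (20 * 90 - 80 * 10)^2 / (100 * 100 * 30 * 170))
  # symmetric table: no association
  rs1 <- ror_stats(7, 7, 7, 7)
  expect_equal(rs1$ror, 1)
  expect_lt(rs1$ci_low, 1)
  expect_gt(rs1$ci_high, 1)
  expect_equal(prr_stats(7, 7, 7, 7), 1)
  expect_equal(chi_square_stat(7, 7, 7, 7), 0)
})

test_that("statistics agree with a brute-force reference on random tables", {
  set.seed(101)
  n <- 1000
  a <- sample(1:500, n, TRUE); b <- sample(1:5000, n, TRUE)
  c_ <- sample(1:5000, n, TRUE); d <- sample(1:50000, n, TRUE)
  rs <- ror_stats(a, b, c_, d)
  prr <- prr_stats(a, b, c_, d)
  chi <- chi_square_stat(a, b, c_, d)
  for (i in sample(n, 200)) {
    ref <- brute_force_stats(a[i], b[i], c_[i], d[i])
    expect_equal(rs$ror[i], ref$ror, tolerance = 1e-12)
    expect_equal(rs$ci_low[i], ref$ci_low, tolerance = 1e-12)
    expect_equal(rs$ci_high[i], ref$ci_high, tolerance = 1e-12)
    expect_equal(prr[i], ref$prr, tolerance = 1e-12)
    expect_equal(chi[i], ref$chi2, tolerance = 1e-12)
  }
  # chi-square is symmetric in rows/columns and matches the uncorrected
  # Pearson test statistic
  expect_equal(chi_square_stat(a, b, c_, d), chi_square_stat(a, c_, b, d))
  for (i in sample(n, 25)) {
    m <- matrix(c(a[i], b[i], c_[i], d[i]), 2, byrow = TRUE)
    expect_equal(
      chi[i],
      unname(suppressWarnings(stats::chisq.test(m, correct = FALSE)$statistic))
    )
  }
})

test_that("PRR above 1 forces ROR above PRR on all-positive tables", {
  set.seed(202)
  n <- 2000
  a <- sample(1:200, n, TRUE); b <- sample(1:2000, n, TRUE)
  c_ <- sample(1:2000, n, TRUE); d <- sample(1:20000, n, TRUE)
  prr <- prr_stats(a, b, c_, d)
  ror <- ror_stats(a, b, c_, d)$ror
  up <- prr > 1
  expect_true(any(up))
  expect_true(all(ror[up] > prr[up]))
})

test_that("zero cells make statistics not evaluable without correction", {
  expect_true(is.na(ror_stats(0, 10, 5, 100)$ror))
  expect_true(is.na(prr_stats(5, 10, 0, 100)))
  expect_true(is.na(chi_square_stat(0, 0, 5, 100)))
})

test_that("signal flags implement both published criteria", {
  res <- tibble::tibble(
    a = c(16439, 2, 10, 10, 10),
    ror = c(252.24, 900, 1.5, 3, 3),
    ci_low = c(246.74, 200, 0.9, 1.2, 1.2),
    prr = c(234.15, 800, 1.4, 2.5, 1.5),
    chi2 = c(1903496, 500, 2, 10, 10),
    evaluable = c(TRUE, TRUE, TRUE, TRUE, TRUE)
  )
  out <- classify_signals(res, signal_criteria())
  expect_equal(out$ror_signal, c(TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(out$prr_signal, c(TRUE, FALSE, FALSE, TRUE, FALSE))
})

rows_fixture <- function() {
  tibble::tibble(
    caseid = as.character(1:8),
    ingredient_key = c("x", "x", "x", "y", "y", "y", "y", "z"),
    is_event = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    matched_pts = replicate(8, character(0), simplify = FALSE)
  )
}

test_that("analysis builds per-drug tables against the pooled background", {
  res <- analyze_signals(rows_fixture())
  expect_s3_class(res, "faers_signals")
  expect_equal(res$ingredient_key, c("x", "y")) # z has a = 0, dropped
  x <- res[res$ingredient_key == "x", ]
  expect_equal(c(x$a, x$b, x$c, x$d), c(2, 1, 1, 4))
  expect_true(all(res$evaluable))
  g <- glance(res)
  expect_equal(g$n_rows, 8L)
  expect_equal(g$n_event_rows, 3L)
  # a + c equals the total number of event rows for every drug
  expect_true(all(res$a + res$c == 3))
})

test_that("single-drug datasets are not evaluable (no background)", {
  rows <- tibble::tibble(
    caseid = as.character(1:4),
    ingredient_key = "only",
    is_event = c(TRUE, TRUE, FALSE, FALSE),
    matched_pts = replicate(4, character(0), simplify = FALSE)
  )
  res <- analyze_signals(rows)
  expect_false(res$evaluable)
  expect_false(res$ror_signal)
  expect_true(is.na(res$ror))
})

test_that("Haldane correction is opt-in and marked", {
  rows <- tibble::tibble(
    caseid = as.character(1:8),
    ingredient_key = c("x", "x", "y", "y", "y", "y", "z", "z"),
    is_event = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    matched_pts = replicate(8, character(0), simplify = FALSE)
  )
  plain <- analyze_signals(rows)
  x <- plain[plain$ingredient_key == "x", ]
  expect_false(x$evaluable) # b = 0
  hald <- analyze_signals(rows, haldane = TRUE)
  xh <- hald[hald$ingredient_key == "x", ]
  expect_true(xh$evaluable)
  expect_true(xh$corrected)
  expect_false(hald$corrected[hald$ingredient_key == "y"])
})

test_that("build_contingency counts cells directly", {
  rows <- tibble::tibble(
    caseid = as.character(1:4),
    ingredient_key = c("X", "X", "Y", "Y"),
    is_event = c(TRUE, FALSE, TRUE, FALSE),
    matched_pts = replicate(4, character(0), simplify = FALSE)
  )
  t1 <- build_contingency(rows, "X")
  expect_equal(c(t1$a, t1$b, t1$c, t1$d), c(1, 1, 1, 1))
  t2 <- build_contingency(dplyr::filter(rows, ingredient_key == "X"), "X")
  expect_equal(c(t2$c, t2$d), c(0, 0))
  t3 <- build_contingency(rows, "absent")
  expect_equal(c(t3$a, t3$b), c(0, 0))
})

test_that("ranking orders by the chosen field with alphabetical ties", {
  res <- analyze_signals(rows_fixture())
  by_count <- rank_signals(res, "case_count")
  expect_equal(by_count$ingredient_key[1], "x") # a: x=2, y=1
  tied <- res
  tied$a <- c(5, 5)
  expect_equal(rank_signals(tied, "case_count")$ingredient_key, c("x", "y"))
  expect_equal(nrow(rank_signals(res, "ror", top_n = 1)), 1L)
})

test_that("counting units and role filters change the unit of analysis", {
  cases <- tibble::tibble(primaryid = c("11", "21"), caseid = c("1", "2"))
  drug <- tibble::tibble(
    primaryid = c("11", "11", "11", "21"),
    drug_seq = c(1L, 2L, 3L, 1L),
    role_cod = c("PS", "PS", "SS", "PS"),
    drugname = c("a", "a", "b", "c"),
    ingredient_key = c("metformin", "metformin", "linezolid", "propofol"),
    mapped = TRUE
  )
  reac <- tibble::tibble(
    primaryid = c("11", "11", "21"),
    pt = c("Lactic acidosis", "Nausea", "Rash"),
    pt_cod = c(10023676L, NA, NA)
  )
  flags <- flag_event_cases(reac, default_event_definition())
  # duplicate PS entries of one key collapse to one row; SS excluded
  rows <- build_case_rows(cases, drug, flags)
  expect_equal(nrow(rows), 2L)
  expect_setequal(rows$ingredient_key, c("metformin", "propofol"))
  # anyrole unit admits the SS drug
  rows_any <- build_case_rows(cases, drug, flags, counting_unit = "case-drug-anyrole")
  expect_setequal(rows_any$ingredient_key, c("metformin", "linezolid", "propofol"))
  # case-drug-reaction unit: one row per distinct reaction PT
  rows_pt <- build_case_rows(cases, drug, flags,
    reac = reac, counting_unit = "case-drug-reaction",
    event_def = default_event_definition()
  )
  expect_equal(nrow(rows_pt), 3L) # metformin x 2 PTs + propofol x 1
  expect_equal(sum(rows_pt$is_event), 1L)
  # empty case set
  expect_equal(nrow(build_case_rows(cases[0, ], drug, flags)), 0L)
})

test_that("PT-level breakdown concentrates where events were planted", {
  cfg <- synth_config(
    n_reports = 800, n_quarters = 2, duplicate_rate = 0, deletion_rate = 0,
    seed = 42,
    background_event_prob = 0.15,
    event_pt_weights = c(
      "Lactic acidosis" = 1,
      "Blood lactic acid increased" = 0,
      "Hyperlactacidaemia" = 0
    ),
    multi_pt_prob = 0
  )
  dir <- withr::local_tempdir()
  man <- generate_faers_package(cfg, dir)
  pc <- pipeline_config(dir, man$quarters, drug_map_path = example_map_path())
  run <- run_faers_pipeline(pc)
  bd <- run$pt_breakdown$breakdown
  other <- bd[bd$pt_name != "Lactic acidosis", ]
  expect_true(all(other$a == 0))
  la <- bd[bd$pt_name == "Lactic acidosis", ]
  expect_gt(sum(la$a), 0)
  # per-PT counts sum to at least the combined count for every key
  combined <- tidy(run$signals)
  per_key <- dplyr::summarise(dplyr::group_by(bd, ingredient_key), s = sum(a))
  joined <- dplyr::inner_join(combined, per_key, by = "ingredient_key")
  expect_true(all(joined$s >= joined$a))
})
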