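# Shared fixture builders; everything is generated in code at test time.

tiny_config <- function(...) {
  synth_config(
    n_reports = 400,
    n_quarters = 2,
    duplicate_rate = 0,
    deletion_rate = 0,
    seed = 42,
    ...
  )
}

# A small hand-built quarter bundle exercising every table.
tiny_bundle <- function() {
  list(
    demo = tibble::tibble(
      primaryid = c("10011", "10021", "10031"),
      caseid = c("1001", "1002", "1003"),
      fda_dt = c("20230110", "20230215", "20230320"),
      event_dt = c("20230101", "202302", NA),
      age = c(62, NA, 2),
      age_cod = c("YR", NA, "DEC"),
      sex = c("F", "M", NA),
      occp_cod = c("MD", "PH", NA),
      reporter_country = c("US", "FR", NA),
      occr_country = c("US", "FR", "JP")
    ),
    drug = tibble::tibble(
      primaryid = c("10011", "10011", "10021", "10031"),
      drug_seq = c(1L, 2L, 1L, 1L),
      role_cod = c("PS", "SS", "PS", "PS"),
      drugname = c("Metformin Hydrochloride", "ZYVOX", "Lipitor", "Propofol"),
      prod_ai = c(NA, NA, NA, NA)
    ),
    reac = tibble::tibble(
      primaryid = c("10011", "10011", "10021", "10031"),
      pt = c("Lactic acidosis", "Nausea", "Headache", "Hyperlactacidaemia"),
      pt_cod = c(10023676L, NA, NA, 10020660L)
    ),
    ther = tibble::tibble(
      primaryid = c("10011", "10031"),
      dsg_drug_seq = c(1L, 1L),
      start_dt = c("20221201", "20230301"),
      end_dt = c(NA, NA)
    ),
    outc = tibble::tibble(
      primaryid = c("10011", "10011", "10031"),
      outc_cod = c("HO", "LT", "DE")
    )
  )
}

# Random well-formed bundle for round-trip property tests.
random_bundle <- function(n = 20) {
  ids <- sprintf("%d1", seq_len(n) + 5000)
  list(
    demo = tibble::tibble(
      primaryid = ids,
      caseid = as.character(seq_len(n) + 5000),
      fda_dt = format(as.Date("2023-01-01") + sample(0:360, n, TRUE), "%Y%m%d"),
      event_dt = ifelse(stats::runif(n) < 0.8,
        format(as.Date("2022-12-01") + sample(0:300, n, TRUE), "%Y%m%d"),
        NA_character_
      ),
      age = ifelse(stats::runif(n) < 0.8, sample(1:95, n, TRUE), NA_real_),
      age_cod = ifelse(stats::runif(n) < 0.8, sample(c("YR", "MON", "DEC"), n, TRUE), NA),
      sex = sample(c("F", "M", NA), n, TRUE),
      occp_cod = sample(c("MD", "PH", "OT", "CN", "LW", NA), n, TRUE),
      reporter_country = sample(c("US", "FR", "JP", NA), n, TRUE),
      occr_country = sample(c("US", "FR", "JP", NA), n, TRUE)
    ),
    drug = tibble::tibble(
      primaryid = rep(ids, each = 2),
      drug_seq = rep(1:2, n),
      role_cod = sample(c("PS", "SS", "C", "I"), 2 * n, TRUE),
      drugname = sample(c("Metformin", "ZYVOX", "Propofol", "Caféine"), 2 * n, TRUE),
      prod_ai = sample(c("METFORMIN HYDROCHLORIDE", NA), 2 * n, TRUE)
    ),
    reac = tibble::tibble(
      primaryid = rep(ids, each = 2),
      pt = sample(c("Lactic acidosis", "Nausea", "Rash"), 2 * n, TRUE),
      pt_cod = sample(c(10023676L, NA), 2 * n, TRUE)
    ),
    ther = tibble::tibble(
      primaryid = ids,
      dsg_drug_seq = rep(1L, n),
      start_dt = format(as.Date("2022-10-01") + sample(0:300, n, TRUE), "%Y%m%d"),
      end_dt = rep(NA_character_, n)
    ),
    outc = tibble::tibble(
      primaryid = ids,
      outc_cod = sample(c("DE", "LT", "HO", "OT"), n, TRUE)
    )
  )
}

example_map_path <- function() {
  system.file("extdata", "example_drug_map.csv", package = "faerslahl")
}

# Independent brute-force reference statistics, composed differently from
# the implementation (odds as a/c over b/d; chi-square from expected counts).
brute_force_stats <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  or <- (a / c) / (b / d)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  prr <- (a * (c + d)) / (c * (a + b))
  obs <- c(a, b, c, d)
  rowt <- c(a + b, a + b, c + d, c + d)
  colt <- c(a + c, b + d, a + c, b + d)
  n <- a + b + c + d
  expd <- rowt * colt / n
  list(
    ror = or,
    ci_low = exp(log(or) - 1.96 * se),
    ci_high = exp(log(or) + 1.96 * se),
    prr = prr,
    chi2 = sum((obs - expd)^2 / expd)
  )
}
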