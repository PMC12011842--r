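#' Default drug vocabulary for the synthetic generator
#'
#' Sixteen products with verbatim-style names (brand names, salt suffixes,
#' mixed case) mapping to single-ingredient keys, with marginal
#' probabilities of being the primary suspect of a report. The brand names
#' (ZYVOX, Lipitor) are resolvable through the shipped example drug map,
#' so a full pipeline run on synthetic data exercises name standardization.
#'
#' @return A tibble `product_name`, `ingredient_key`, `prob` (sums to 1).
#' @export
default_drug_vocabulary <- function() {
  tibble::tribble(
    ~product_name, ~ingredient_key, ~prob,
    "Metformin Hydrochloride", "metformin", 0.1000,
    "ZYVOX", "linezolid", 0.0075,
    "Amlodipine Besylate", "amlodipine", 0.0900,
    "Salbutamol", "salbutamol", 0.0700,
    "PARACETAMOL", "paracetamol", 0.1200,
    "Stavudine", "stavudine", 0.0100,
    "Telbivudine", "telbivudine", 0.0050,
    "Nevirapine", "nevirapine", 0.0100,
    "Propofol", "propofol", 0.0300,
    "Colchicine", "colchicine", 0.0200,
    "Lisinopril", "lisinopril", 0.0900,
    "Lipitor", "atorvastatin", 0.1200,
    "Omeprazole", "omeprazole", 0.1000,
    "Ibuprofen", "ibuprofen", 0.1100,
    "Sertraline Hydrochloride", "sertraline", 0.0800,
    "Insulin Glargine", "insulin glargine", 0.0375
  )
}

synth_noise_pts <- c(
  "Nausea", "Headache", "Dizziness", "Rash", "Vomiting", "Diarrhoea",
  "Fatigue", "Pyrexia", "Pruritus", "Dyspnoea", "Abdominal pain",
  "Anaemia", "Hypotension", "Renal impairment", "Hepatic enzyme increased",
  "Insomnia", "Arthralgia", "Myalgia", "Cough", "Constipation",
  "Oedema peripheral", "Tachycardia", "Confusional state", "Weight decreased",
  "Hyperkalaemia"
)

#' Configuration of the synthetic FAERS-like generator
#'
#' Parameterizes a generator of spontaneous-report quarterly packages with
#' known ground truth. Event status is sampled per report from the primary
#' suspect's planted odds ratio: the logit of `background_event_prob` is
#' shifted by the log odds ratio, so the per-key 2x2 tables are analytically
#' known and a planted odds ratio of 1 means no association. Duplicate
#' report versions perturb only the receipt date, report identifier and
#' (optionally) demographics — never drugs or reactions — so deduplication
#' correctness is isolatable. Therapy start precedes the event date by an
#' exponential lag.
#'
#' The defaults emulate the corpus conditions the package is validated
#' against: 20,000 reports over four 2023 quarters, a 5% background event
#' probability, one strongly associated drug (linezolid, odds ratio 10,
#' expected event-report count near 50), event PT weights proportional to
#' the published per-term case counts (26,364 : 4,310 : 2,103), about 1.8%
#' of event cases carrying a second event PT, and an exponential
#' therapy-to-onset lag with a 25-day median (mean 36).
#'
#' @param n_reports Number of true underlying cases.
#' @param n_quarters Number of quarterly packages.
#' @param start_date First day of the first quarter (receipt-date window).
#' @param drug_vocabulary Tibble `product_name`, `ingredient_key`, `prob`.
#' @param drugs_per_report_dist Named probability vector over drug-entry
#'   counts per report (`"1"`, `"2"`, ...).
#' @param reactions_per_report_dist Named probability vector over
#'   non-event reaction counts per report.
#' @param background_event_prob Event probability for reports whose primary
#'   suspect has no planted association.
#' @param planted_odds_ratios Named numeric vector, ingredient key to odds
#'   ratio (>= 0); keys absent here have odds ratio 1.
#' @param duplicate_rate Fraction of cases emitted as two report versions.
#' @param deletion_rate Fraction of cases listed in DELETED files.
#' @param missing_age_rate,missing_sex_rate Missingness fractions.
#' @param event_pt_weights Named probability vector over the event PT set.
#' @param multi_pt_prob Probability that an event case receives a second
#'   event PT.
#' @param onset_lag_mean_days Mean of the exponential therapy-start-to-event
#'   lag.
#' @param reporting_delay_max_days Event-to-receipt delay, uniform on
#'   `[0, max]`.
#' @param seed Integer seed; identical config and seed give byte-identical
#'   output files.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_reports = 20000,
                         n_quarters = 4,
                         start_date = as.Date("2023-01-01"),
                         drug_vocabulary = default_drug_vocabulary(),
                         drugs_per_report_dist = c("1" = 0.55, "2" = 0.30, "3" = 0.15),
                         reactions_per_report_dist = c("1" = 0.50, "2" = 0.30, "3" = 0.20),
                         background_event_prob = 0.05,
                         planted_odds_ratios = c(linezolid = 10),
                         duplicate_rate = 0.10,
                         deletion_rate = 0.02,
                         missing_age_rate = 0.15,
                         missing_sex_rate = 0.10,
                         event_pt_weights = c(
                           "Lactic acidosis" = 26364,
                           "Blood lactic acid increased" = 4310,
                           "Hyperlactacidaemia" = 2103
                         ) / (26364 + 4310 + 2103),
                         multi_pt_prob = 0.018,
                         onset_lag_mean_days = 36,
                         reporting_delay_max_days = 60,
                         seed = 1L) {
  config <- list(
    n_reports = n_reports, n_quarters = n_quarters, start_date = start_date,
    drug_vocabulary = drug_vocabulary,
    drugs_per_report_dist = drugs_per_report_dist,
    reactions_per_report_dist = reactions_per_report_dist,
    background_event_prob = background_event_prob,
    planted_odds_ratios = planted_odds_ratios,
    duplicate_rate = duplicate_rate, deletion_rate = deletion_rate,
    missing_age_rate = missing_age_rate, missing_sex_rate = missing_sex_rate,
    event_pt_weights = event_pt_weights, multi_pt_prob = multi_pt_prob,
    onset_lag_mean_days = onset_lag_mean_days,
    reporting_delay_max_days = reporting_delay_max_days,
    seed = as.integer(seed)
  )
  class(config) <- "synth_config"
  validate_synth_config(config)
  config
}

#' @rdname synth_config
#' @param config A `synth_config` list.
#' @export
validate_synth_config <- function(config) {
  fail <- function(field, why) {
    stop(sprintf("invalid synth_config: field '%s' %s", field, why), call. = FALSE)
  }
  if (!is.numeric(config$n_reports) || config$n_reports < 1) {
    fail("n_reports", "must be a positive count")
  }
  if (!is.numeric(config$n_quarters) || config$n_quarters < 1) {
    fail("n_quarters", "must be a positive count")
  }
  vocab <- config$drug_vocabulary
  if (!is.data.frame(vocab) || nrow(vocab) == 0L) {
    fail("drug_vocabulary", "must be a non-empty data frame")
  }
  if (abs(sum(vocab$prob) - 1) > 1e-9 || any(vocab$prob < 0)) {
    fail("drug_vocabulary", "probabilities must be non-negative and sum to 1")
  }
  for (field in c("drugs_per_report_dist", "reactions_per_report_dist",
                  "event_pt_weights")) {
    d <- config[[field]]
    if (is.null(names(d)) || any(d < 0) || abs(sum(d) - 1) > 1e-9) {
      fail(field, "must be a named distribution summing to 1 (within 1e-9)")
    }
  }
  for (field in c("background_event_prob", "multi_pt_prob")) {
    p <- config[[field]]
    if (!is.numeric(p) || p < 0 || p > 1) fail(field, "must be in [0, 1]")
  }
  for (field in c("duplicate_rate", "deletion_rate", "missing_age_rate",
                  "missing_sex_rate")) {
    p <- config[[field]]
    if (!is.numeric(p) || p < 0 || p >= 1) fail(field, "must be in [0, 1)")
  }
  if (any(config$planted_odds_ratios < 0) ||
      (length(config$planted_odds_ratios) > 0 &&
       is.null(names(config$planted_odds_ratios)))) {
    fail("planted_odds_ratios", "must be a named vector of odds ratios >= 0")
  }
  if (!is.numeric(config$seed) || is.na(config$seed)) {
    fail("seed", "must be an integer")
  }
  invisible(config)
}

quarter_label <- function(dates) {
  sprintf("%dQ%d", as.integer(format(dates, "%Y")),
          (as.integer(format(dates, "%m")) - 1L) %/% 3L + 1L)
}

synth_quarter_labels <- function(config) {
  starts <- seq(config$start_date, by = "3 months", length.out = config$n_quarters)
  quarter_label(starts)
}

fmt8 <- function(dates) format(dates, "%Y%m%d")

sample_dist <- function(n, dist) {
  as.integer(sample(names(dist), n, replace = TRUE, prob = dist))
}

# Core sampling shared by the full generator and the fast ground-truth
# path: primary-suspect assignment, event status, deletion and duplication
# flags. Draw order here is a compatibility contract — synth_cases() must
# reproduce exactly these values for a given seed.
synth_core <- function(config) {
  n <- config$n_reports
  vocab <- config$drug_vocabulary
  ps_idx <- sample.int(nrow(vocab), n, replace = TRUE, prob = vocab$prob)
  ps_key <- vocab$ingredient_key[ps_idx]
  or <- rep(1, n)
  planted <- config$planted_odds_ratios
  hit <- ps_key %in% names(planted)
  or[hit] <- planted[ps_key[hit]]
  p_event <- stats::plogis(stats::qlogis(config$background_event_prob) + log(or))
  is_event <- stats::runif(n) < p_event
  is_deleted <- stats::runif(n) < config$deletion_rate
  has_duplicate <- stats::runif(n) < config$duplicate_rate
  tibble::tibble(
    caseid = sprintf("%07d", seq_len(n)),
    ps_idx = ps_idx,
    ps_key = ps_key,
    is_event = is_event,
    is_deleted = is_deleted,
    has_duplicate = has_duplicate
  )
}

truth_from_core <- function(core, vocab) {
  kept <- core[!core$is_deleted, ]
  n_total <- nrow(kept)
  n_event <- sum(kept$is_event)
  tibble::tibble(ingredient_key = sort(unique(vocab$ingredient_key))) |>
    dplyr::left_join(
      kept |>
        dplyr::group_by(ingredient_key = .data$ps_key) |>
        dplyr::summarise(
          a = sum(.data$is_event), b = sum(!.data$is_event),
          .groups = "drop"
        ),
      by = "ingredient_key"
    ) |>
    dplyr::mutate(
      a = dplyr::coalesce(.data$a, 0L),
      b = dplyr::coalesce(.data$b, 0L),
      c = n_event - .data$a,
      d = (n_total - n_event) - .data$b
    )
}

#' Ground-truth contingency tables without writing files
#'
#' Runs only the core sampling of the generator (primary-suspect
#' assignment, event status, deletion flags) and tabulates the post-dedup,
#' post-deletion 2x2 table per ingredient key. Identical to the
#' `ground_truth` component of [generate_faers_package()] for the same
#' config — this is the fast path for Monte-Carlo calibration studies that
#' need many seeds but no files.
#'
#' @param config A [synth_config()].
#' @return A tibble `ingredient_key`, `a`, `b`, `c`, `d`.
#' @export
synth_ground_truth <- function(config) {
  validate_synth_config(config)
  set.seed(config$seed)
  truth_from_core(synth_core(config), config$drug_vocabulary)
}

#' Sample the full synthetic case table
#'
#' One row per true underlying case, with demographics, dates, drugs,
#' reactions, outcomes, therapy start, and the deletion/duplication flags
#' used by [generate_faers_package()]. Deterministic given the config seed.
#'
#' @param config A [synth_config()].
#' @return A tibble with one row per case.
#' @export
synth_cases <- function(config) {
  validate_synth_config(config)
  set.seed(config$seed)
  core <- synth_core(config)
  n <- config$n_reports
  vocab <- config$drug_vocabulary

  # receipt dates uniform over the quarter window; event precedes receipt
  window_days <- as.integer(
    seq(config$start_date, by = "3 months", length.out = config$n_quarters + 1)[config$n_quarters + 1] -
      config$start_date
  )
  fda_date <- config$start_date + floor(stats::runif(n) * window_days)
  event_date <- fda_date - floor(stats::runif(n) * (config$reporting_delay_max_days + 1))
  onset_lag <- round(stats::rexp(n, rate = 1 / config$onset_lag_mean_days))
  ther_start <- event_date - onset_lag
  ther_missing <- stats::runif(n) < 0.2

  age <- round(pmin(pmax(stats::rnorm(n, 62, 15), 18), 95))
  age_cod <- rep("YR", n)
  in_dec <- stats::runif(n) < 0.03
  age[in_dec] <- round(age[in_dec] / 10)
  age_cod[in_dec] <- "DEC"
  age_missing <- stats::runif(n) < config$missing_age_rate
  age[age_missing] <- NA_real_
  age_cod[age_missing] <- NA_character_

  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.52, 0.48))
  sex[stats::runif(n) < config$missing_sex_rate] <- NA_character_

  occp <- sample(c("MD", "PH", "OT", "CN", "LW", NA),
    n, replace = TRUE,
    prob = c(0.31, 0.28, 0.26, 0.09, 0.004, 0.056)
  )
  countries <- c("US", "FR", "DE", "IT", "GB", "JP", "CN", "CA", "ES", "AU",
                 "BR", "IN", "NL", "ZA")
  country_prob <- c(0.33, 0.12, 0.08, 0.06, 0.06, 0.06, 0.05, 0.05, 0.04,
                    0.03, 0.03, 0.03, 0.03, 0.03)
  country <- sample(countries, n, replace = TRUE, prob = country_prob)

  # non-exclusive outcome codes; event cases are nearly always serious
  outc_prob_event <- c(HO = 0.72, LT = 0.30, DE = 0.22, DS = 0.013,
                       CA = 0.003, RI = 0.009, OT = 0.53)
  outc_prob_other <- c(HO = 0.35, LT = 0.08, DE = 0.06, DS = 0.01,
                       CA = 0.002, RI = 0.005, OT = 0.30)
  draw <- matrix(stats::runif(n * 7), n, 7)
  prob_mat <- matrix(rep(outc_prob_other, each = n), n, 7)
  prob_mat[core$is_event, ] <- matrix(
    rep(outc_prob_event, each = sum(core$is_event)), sum(core$is_event), 7
  )
  hit_mat <- draw < prob_mat
  outcomes <- purrr::map(seq_len(n), ~ names(outc_prob_event)[hit_mat[.x, ]])

  # extra (non-primary-suspect) drug entries never alter event probability
  n_drugs <- sample_dist(n, config$drugs_per_report_dist)
  extra_counts <- pmax(n_drugs - 1L, 0L)
  extra_idx <- purrr::map(extra_counts, function(k) {
    if (k == 0L) integer(0) else sample.int(nrow(vocab), k, replace = TRUE, prob = vocab$prob)
  })
  extra_roles <- purrr::map(extra_counts, function(k) {
    if (k == 0L) character(0) else sample(c("SS", "C", "I"), k, replace = TRUE,
                                          prob = c(0.5, 0.4, 0.1))
  })

  # reactions: noise PTs for everyone, event PTs on top for event cases
  n_reac <- sample_dist(n, config$reactions_per_report_dist)
  noise_pts <- purrr::map(n_reac, ~ sample(synth_noise_pts, .x))
  pt_names <- names(config$event_pt_weights)
  primary_pt <- sample(pt_names, n, replace = TRUE, prob = config$event_pt_weights)
  second <- stats::runif(n) < config$multi_pt_prob
  second_pt <- purrr::map_chr(seq_len(n), function(i) {
    if (!second[i] || length(pt_names) < 2L) return(NA_character_)
    rest <- setdiff(pt_names, primary_pt[i])
    w <- config$event_pt_weights[rest]
    sample(rest, 1, prob = w / sum(w))
  })
  reac_pts <- purrr::map(seq_len(n), function(i) {
    evt <- if (core$is_event[i]) {
      c(primary_pt[i], if (!is.na(second_pt[i])) second_pt[i])
    } else {
      character(0)
    }
    c(evt, noise_pts[[i]])
  })

  dplyr::bind_cols(
    core,
    tibble::tibble(
      quarter = quarter_label(fda_date),
      fda_dt = fmt8(fda_date),
      event_dt = fmt8(event_date),
      ther_start_dt = ifelse(ther_missing, NA_character_, fmt8(ther_start)),
      age = age, age_cod = age_cod, sex = sex, occp_cod = occp,
      country = country,
      outcomes = outcomes,
      ps_product = vocab$product_name[core$ps_idx],
      extra_products = purrr::map(extra_idx, ~ vocab$product_name[.x]),
      extra_roles = extra_roles,
      reac_pts = reac_pts
    )
  )
}

#' Generate a FAERS-like quarterly package set with known ground truth
#'
#' Samples the case table ([synth_cases()]), emits duplicate report
#' versions (shared CASEID, differing FDA_DT, or tied FDA_DT with a lower
#' PRIMARYID — the true version always wins the dedup rule), writes the
#' DEMO/DRUG/REAC/THER/OUTC files per quarter plus DELETED lists for
#' quarters from 2019 onwards, and records the ground-truth per-key 2x2
#' tables (post-dedup, post-deletion).
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory, created if needed.
#' @return A list of class `synth_manifest`: `dir`, `quarters`, `files`
#'   (per-quarter path vectors), `ground_truth` tibble, `deleted_caseids`,
#'   `n_cases` (post-deletion case count), `config`. Also written to disk
#'   as `ground_truth.csv` and `manifest.json`.
#' @export
generate_faers_package <- function(config, out_dir) {
  validate_synth_config(config)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop(sprintf("cannot create output directory: %s", out_dir), call. = FALSE)
  }
  quarters <- synth_quarter_labels(config)
  eligible <- as.integer(substr(quarters, 1, 4)) >= 2019
  if (config$deletion_rate > 0 && !any(eligible)) {
    stop(paste(
      "invalid synth_config: field 'deletion_rate' is positive but no quarter",
      "is 2019 or later, so no DELETED list can carry the deletions"
    ), call. = FALSE)
  }
  cases <- synth_cases(config)
  vocab <- config$drug_vocabulary
  ground_truth <- truth_from_core(cases, vocab)

  # duplicate versions: version 2 is the true record; version 1 is stale,
  # with an earlier receipt date (or a tied date, exercising the PRIMARYID
  # tie-break). Drugs and reactions are copied verbatim.
  dups <- cases[cases$has_duplicate, ]
  tie <- stats::runif(nrow(dups)) < 0.5
  dup_fda <- as.Date(dups$fda_dt, "%Y%m%d") - ifelse(tie, 0L, sample(7:90, nrow(dups), replace = TRUE))
  dup_fda <- pmax(dup_fda, config$start_date)
  dups$fda_dt <- fmt8(dup_fda)
  dups$quarter <- quarter_label(dup_fda)
  # stale versions may carry stale demographics
  dups$age <- ifelse(!is.na(dups$age) & stats::runif(nrow(dups)) < 0.3,
                     dups$age + 1, dups$age)
  cases$version <- ifelse(cases$has_duplicate, 2L, 1L)
  dups$version <- 1L
  all_versions <- dplyr::bind_rows(cases, dups) |>
    dplyr::mutate(primaryid = paste0(.data$caseid, .data$version))

  deleted_caseids <- cases$caseid[cases$is_deleted]
  deleted_quarter <- if (length(deleted_caseids) > 0) {
    sample(quarters[eligible], length(deleted_caseids), replace = TRUE)
  } else {
    character(0)
  }

  files <- list()
  for (q in quarters) {
    v <- all_versions[all_versions$quarter == q, ]
    demo <- tibble::tibble(
      primaryid = v$primaryid, caseid = v$caseid, fda_dt = v$fda_dt,
      event_dt = v$event_dt, age = v$age, age_cod = v$age_cod, sex = v$sex,
      occp_cod = v$occp_cod, reporter_country = v$country,
      occr_country = v$country
    )
    drug <- dplyr::bind_rows(
      tibble::tibble(
        primaryid = v$primaryid, drug_seq = 1L, role_cod = "PS",
        drugname = v$ps_product, prod_ai = NA_character_
      ),
      tidyr::unnest(
        tibble::tibble(
          primaryid = v$primaryid,
          drugname = v$extra_products, role_cod = v$extra_roles
        ),
        cols = c("drugname", "role_cod")
      ) |>
        dplyr::group_by(.data$primaryid) |>
        dplyr::mutate(drug_seq = dplyr::row_number() + 1L) |>
        dplyr::ungroup() |>
        dplyr::mutate(prod_ai = NA_character_)
    ) |>
      dplyr::arrange(.data$primaryid, .data$drug_seq) |>
      dplyr::select("primaryid", "drug_seq", "role_cod", "drugname", "prod_ai")
    event_codes <- stats::setNames(
      default_event_definition()$pt_code,
      default_event_definition()$pt_name
    )
    reac <- tidyr::unnest(
      tibble::tibble(primaryid = v$primaryid, pt = v$reac_pts),
      cols = "pt"
    ) |>
      dplyr::mutate(pt_cod = unname(event_codes[.data$pt]))
    ther <- tibble::tibble(
      primaryid = v$primaryid, dsg_drug_seq = 1L,
      start_dt = v$ther_start_dt, end_dt = NA_character_
    ) |>
      dplyr::filter(!is.na(.data$start_dt))
    outc <- tidyr::unnest(
      tibble::tibble(primaryid = v$primaryid, outc_cod = v$outcomes),
      cols = "outc_cod"
    )
    paths <- write_faers_quarter(
      list(demo = demo, drug = drug, reac = reac, ther = ther, outc = outc),
      out_dir, q
    )
    if (eligible[match(q, quarters)]) {
      del_path <- write_deleted_cases(
        sort(deleted_caseids[deleted_quarter == q]), out_dir, q
      )
      paths <- c(paths, deleted = del_path)
    }
    files[[q]] <- paths
  }

  manifest <- list(
    dir = out_dir,
    quarters = quarters,
    files = files,
    ground_truth = ground_truth,
    deleted_caseids = deleted_caseids,
    n_cases = sum(!cases$is_deleted),
    config = config
  )
  class(manifest) <- "synth_manifest"
  readr::write_csv(ground_truth, file.path(out_dir, "ground_truth.csv"))
  jsonlite::write_json(
    list(
      quarters = quarters,
      n_cases = manifest$n_cases,
      n_deleted = length(deleted_caseids),
      seed = config$seed,
      ground_truth = ground_truth
    ),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  manifest
}

#' Keys whose ground-truth table satisfies the signal criteria
#'
#' The reference answer for pipeline-recovery tests: applies the ROR and/or
#' PRR criteria directly to the generator's ground-truth 2x2 tables.
#'
#' @param manifest A `synth_manifest` from [generate_faers_package()], or
#'   any object with a `ground_truth` tibble.
#' @param criteria A [signal_criteria()].
#' @param which Which rule set must fire: `"either"` (default), `"ror"`,
#'   `"prr"`, or `"both"`.
#' @return Character vector of ingredient keys.
#' @export
ground_truth_signals <- function(manifest, criteria = signal_criteria(),
                                 which = c("either", "ror", "prr", "both")) {
  which <- match.arg(which)
  gt <- manifest$ground_truth
  res <- dplyr::bind_cols(
    gt,
    ror_stats(gt$a, gt$b, gt$c, gt$d),
    tibble::tibble(
      prr = prr_stats(gt$a, gt$b, gt$c, gt$d),
      chi2 = chi_square_stat(gt$a, gt$b, gt$c, gt$d)
    )
  ) |>
    dplyr::mutate(
      evaluable = .data$a > 0 & .data$b > 0 & .data$c > 0 & .data$d > 0
    ) |>
    classify_signals(criteria)
  flag <- switch(which,
    either = res$ror_signal | res$prr_signal,
    ror = res$ror_signal,
    prr = res$prr_signal,
    both = res$ror_signal & res$prr_signal
  )
  sort(res$ingredient_key[flag])
}
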