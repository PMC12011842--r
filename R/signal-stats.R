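#' Signal criteria thresholds
#'
#' The standard case/non-case signal rules: an ROR signal requires
#' ROR > 1, the lower 95% confidence limit > 1, and at least `min_a`
#' reports; a PRR signal requires PRR >= 2, Pearson chi-square > 4, and at
#' least `min_a` reports.
#'
#' @param ror_point_min ROR point estimate must exceed this (default 1).
#' @param ror_ci_low_min Lower 95% CI limit must exceed this (default 1).
#' @param min_a Minimum number of event reports with the drug (default 3).
#' @param prr_min PRR threshold, inclusive (default 2).
#' @param chi2_min Chi-square threshold, exclusive (default 4).
#' @return A list of class `signal_criteria`.
#' @export
signal_criteria <- function(ror_point_min = 1, ror_ci_low_min = 1, min_a = 3,
                            prr_min = 2, chi2_min = 4) {
  crit <- list(
    ror_point_min = ror_point_min, ror_ci_low_min = ror_ci_low_min,
    min_a = min_a, prr_min = prr_min, chi2_min = chi2_min
  )
  stopifnot(all(vapply(crit, function(x) is.numeric(x) && x > 0, logical(1))))
  structure(crit, class = "signal_criteria")
}

#' Build case-drug analysis rows
#'
#' The counting unit of the disproportionality analysis. Under the default
#' `"case-drug"` unit, each deduplicated case contributes one row per
#' distinct ingredient key among its primary-suspect (PS) drugs; the row is
#' an event row iff the case is an event case. `"case-drug-anyrole"` admits
#' all drug roles; `"case-drug-reaction"` is the finer unit of one row per
#' (case, ingredient key, distinct reaction PT), where each row's event
#' status is that of its own PT.
#'
#' @param cases Deduplicated case tibble (from [dedup_cases()] /
#'   [apply_deletions()]) with `primaryid`, `caseid`.
#' @param drug Standardized DRUG tibble (from [standardize_drugs()]) with
#'   `primaryid`, `role_cod`, `ingredient_key`.
#' @param event_flags Per-report event flags from [flag_event_cases()].
#' @param reac REAC tibble; required only for the `"case-drug-reaction"`
#'   unit.
#' @param role_filter Drug role codes contributing rows (default `"PS"`;
#'   ignored by the anyrole unit).
#' @param counting_unit One of `"case-drug"`, `"case-drug-anyrole"`,
#'   `"case-drug-reaction"`.
#' @param event_def Event definition; required only for the
#'   `"case-drug-reaction"` unit.
#' @return A tibble with columns `caseid`, `ingredient_key`, `is_event`,
#'   `matched_pts` (list column).
#' @export
build_case_rows <- function(cases, drug, event_flags, reac = NULL,
                            role_filter = "PS",
                            counting_unit = c("case-drug", "case-drug-anyrole",
                                              "case-drug-reaction"),
                            event_def = NULL) {
  counting_unit <- match.arg(counting_unit)
  stopifnot(all(c("primaryid", "caseid") %in% names(cases)))
  stopifnot(all(c("primaryid", "role_cod", "ingredient_key") %in% names(drug)))

  case_drugs <- drug |>
    dplyr::semi_join(cases, by = "primaryid") |>
    dplyr::filter(.data$ingredient_key != "")
  if (counting_unit != "case-drug-anyrole") {
    case_drugs <- dplyr::filter(case_drugs, .data$role_cod %in% role_filter)
  }
  case_drugs <- case_drugs |>
    dplyr::inner_join(dplyr::select(cases, "primaryid", "caseid"), by = "primaryid") |>
    dplyr::distinct(.data$primaryid, .data$caseid, .data$ingredient_key)

  if (counting_unit == "case-drug-reaction") {
    stopifnot(!is.null(reac), !is.null(event_def))
    def_name_l <- tolower(stringr::str_squish(event_def$pt_name))
    pts <- reac |>
      dplyr::semi_join(cases, by = "primaryid") |>
      dplyr::distinct(.data$primaryid, .data$pt) |>
      dplyr::mutate(
        .idx = match(tolower(stringr::str_squish(.data$pt)), def_name_l),
        is_event = !is.na(.data$.idx),
        matched = event_def$pt_name[.data$.idx]
      )
    rows <- case_drugs |>
      dplyr::inner_join(
        dplyr::select(pts, "primaryid", "pt", "is_event", "matched"),
        by = "primaryid", relationship = "many-to-many"
      ) |>
      dplyr::distinct(.data$caseid, .data$ingredient_key, .data$pt,
                      .keep_all = TRUE) |>
      dplyr::mutate(matched_pts = purrr::map(.data$matched, ~ .x[!is.na(.x)])) |>
      dplyr::select("caseid", "ingredient_key", "is_event", "matched_pts")
    return(rows)
  }

  flags <- event_flags |>
    dplyr::select("primaryid", "is_event", "matched_pts")
  case_drugs |>
    dplyr::left_join(flags, by = "primaryid") |>
    dplyr::mutate(
      is_event = dplyr::coalesce(.data$is_event, FALSE),
      matched_pts = purrr::map(.data$matched_pts, ~ .x %||% character(0))
    ) |>
    dplyr::distinct(.data$caseid, .data$ingredient_key, .keep_all = TRUE) |>
    dplyr::select("caseid", "ingredient_key", "is_event", "matched_pts")
}

#' Build a 2x2 contingency table for one drug
#'
#' Cells of the case/non-case table: `a` = rows with the target drug and
#' the event, `b` = target drug without the event, `c` = event with any
#' other drug, `d` = neither.
#'
#' @param rows Analysis rows from [build_case_rows()].
#' @param target_key Ingredient key of the target drug.
#' @return A one-row tibble: `ingredient_key`, `a`, `b`, `c`, `d`, `n`.
#' @export
build_contingency <- function(rows, target_key) {
  stopifnot(nrow(rows) > 0L)
  is_target <- rows$ingredient_key == target_key
  a <- sum(is_target & rows$is_event)
  b <- sum(is_target & !rows$is_event)
  c_ <- sum(!is_target & rows$is_event)
  d <- sum(!is_target & !rows$is_event)
  tibble::tibble(
    ingredient_key = target_key,
    a = a, b = b, c = c_, d = d, n = a + b + c_ + d
  )
}

#' Reporting odds ratio with 95% confidence interval
#'
#' ROR = (a d)/(b c); the 95% CI is computed on the log scale,
#' `exp(log ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. Cells may be
#' real-valued (reconstructed tables). Any zero cell makes the statistic
#' not evaluable and yields `NA` (no Haldane correction here; see
#' [analyze_signals()] for the opt-in correction).
#'
#' @param a,b,c,d Cell counts, vectorized.
#' @return A tibble with columns `ror`, `ci_low`, `ci_high`.
#' @examples
#' ror_stats(20, 80, 10, 90) # ROR 2.25
#' @export
ror_stats <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  ok <- !is.na(a) & !is.na(b) & !is.na(c) & !is.na(d) &
    a > 0 & b > 0 & c > 0 & d > 0
  ror <- ifelse(ok, (a * d) / (b * c), NA_real_)
  se <- ifelse(ok, sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
  tibble::tibble(
    ror = ror,
    ci_low = exp(log(ror) - 1.96 * se),
    ci_high = exp(log(ror) + 1.96 * se)
  )
}

#' Proportional reporting ratio
#'
#' PRR = (a/(a+b)) / (c/(c+d)). Not evaluable (NA) when a denominator or
#' `c` is zero.
#'
#' @param a,b,c,d Cell counts, vectorized.
#' @return Numeric vector of PRR values.
#' @examples
#' prr_stats(20, 80, 10, 90) # 2
#' @export
prr_stats <- function(a, b, c, d) {
  ok <- !is.na(a) & !is.na(b) & !is.na(c) & !is.na(d) &
    (a + b) > 0 & (c + d) > 0 & c > 0
  ifelse(ok, (a / (a + b)) / (c / (c + d)), NA_real_)
}

#' Pearson chi-square statistic of the 2x2 table
#'
#' The uncorrected Pearson statistic
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with `N = a+b+c+d`. No Yates
#' continuity correction is applied: reconstructing printed reference rows
#' confirms the uncorrected form (with the correction, small-count rows
#' would be 0.5-1.3% below their printed statistics). Not evaluable (NA)
#' when any margin is zero.
#'
#' @param a,b,c,d Cell counts, vectorized.
#' @return Numeric vector of chi-square values.
#' @examples
#' chi_square_stat(20, 80, 10, 90)
#' @export
chi_square_stat <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  ok <- !is.na(n) &
    (a + b) > 0 & (c + d) > 0 & (a + c) > 0 & (b + d) > 0
  ifelse(ok,
    n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d)),
    NA_real_
  )
}

#' Apply signal criteria to computed statistics
#'
#' Sets `ror_signal` and `prr_signal` on a results tibble. Both flags are
#' `FALSE` whenever the row is not evaluable or has fewer than `min_a`
#' event reports.
#'
#' @param results Tibble with columns `a`, `ror`, `ci_low`, `prr`, `chi2`,
#'   `evaluable`.
#' @param criteria A [signal_criteria()] object.
#' @return `results` with logical columns `ror_signal`, `prr_signal`.
#' @export
classify_signals <- function(results, criteria = signal_criteria()) {
  results |>
    dplyr::mutate(
      ror_signal = dplyr::coalesce(
        .data$evaluable &
          .data$ror > criteria$ror_point_min &
          .data$ci_low > criteria$ror_ci_low_min &
          .data$a >= criteria$min_a,
        FALSE
      ),
      prr_signal = dplyr::coalesce(
        .data$evaluable &
          .data$prr >= criteria$prr_min &
          .data$chi2 > criteria$chi2_min &
          .data$a >= criteria$min_a,
        FALSE
      )
    )
}

#' Disproportionality analysis over all drugs
#'
#' Builds the per-drug 2x2 table for every distinct ingredient key with at
#' least one row, computes ROR with 95% CI, PRR and the Pearson chi-square,
#' and applies the signal criteria. Keys with any zero cell are marked not
#' evaluable and never flagged (by default; `haldane = TRUE` opts into
#' adding 0.5 to every cell of zero-cell tables, clearly marked in the
#' `corrected` column).
#'
#' Only keys with at least one event report (`a >= 1`) are retained: the
#' analysis is of suspect medications of the event, and keys never reported
#' with it carry no signal information. All rows (including dropped keys')
#' still contribute to the background cells `c` and `d`.
#'
#' @param rows Analysis rows from [build_case_rows()].
#' @param criteria A [signal_criteria()] object.
#' @param haldane If `TRUE`, apply the Haldane-Anscombe +0.5 correction to
#'   tables with a zero cell instead of marking them not evaluable.
#' @return A tibble of class `faers_signals`, one row per ingredient key in
#'   ascending key order: `ingredient_key`, `a`, `b`, `c`, `d`, `ror`,
#'   `ci_low`, `ci_high`, `prr`, `chi2`, `evaluable`, `corrected`,
#'   `ror_signal`, `prr_signal`. Attributes record the criteria and row
#'   totals; see [glance.faers_signals()].
#' @export
analyze_signals <- function(rows, criteria = signal_criteria(), haldane = FALSE) {
  stopifnot(nrow(rows) > 0L)
  n_total <- nrow(rows)
  n_event <- sum(rows$is_event)

  counts <- rows |>
    dplyr::group_by(.data$ingredient_key) |>
    dplyr::summarise(
      a = sum(.data$is_event),
      b = sum(!.data$is_event),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      c = n_event - .data$a,
      d = (n_total - n_event) - .data$b
    ) |>
    dplyr::filter(.data$a >= 1) |>
    dplyr::arrange(.data$ingredient_key)

  zero_cell <- counts$a == 0 | counts$b == 0 | counts$c == 0 | counts$d == 0
  corrected <- haldane & zero_cell
  adj <- ifelse(corrected, 0.5, 0)
  a <- counts$a + adj
  b <- counts$b + adj
  c_ <- counts$c + adj
  d <- counts$d + adj

  res <- dplyr::bind_cols(
    counts,
    ror_stats(a, b, c_, d),
    tibble::tibble(
      prr = prr_stats(a, b, c_, d),
      chi2 = chi_square_stat(a, b, c_, d)
    )
  ) |>
    dplyr::mutate(
      evaluable = !zero_cell | corrected,
      corrected = corrected
    ) |>
    classify_signals(criteria)

  structure(
    res,
    criteria = criteria,
    n_rows = n_total,
    n_event_rows = n_event,
    class = c("faers_signals", class(res))
  )
}

#' Rank signal results
#'
#' Orders the analysis by case count or by signal strength. Ranking by
#' strength (`"ror"` or `"prr"`) considers only evaluable results; ties are
#' broken by ingredient key, ascending.
#'
#' @param results A [analyze_signals()] result.
#' @param by `"case_count"`, `"ror"` or `"prr"`.
#' @param top_n Keep the first `top_n` rows (default all).
#' @return The reordered (and truncated) tibble.
#' @export
rank_signals <- function(results, by = c("case_count", "ror", "prr"),
                         top_n = Inf) {
  by <- match.arg(by)
  field <- switch(by, case_count = "a", ror = "ror", prr = "prr")
  out <- results
  if (by != "case_count") {
    out <- dplyr::filter(out, .data$evaluable)
  }
  out <- dplyr::arrange(out, dplyr::desc(.data[[field]]), .data$ingredient_key)
  if (is.finite(top_n)) {
    out <- dplyr::slice_head(out, n = top_n)
  }
  out
}

#' Per-preferred-term signal breakdown for selected drugs
#'
#' Re-runs the analysis once per preferred term of the event definition,
#' treating that single PT as the event, and reports the count and lower
#' 95% CI limit per (drug, PT). Drugs for which no PT achieves a lower CI
#' limit above 1 are flagged `negative_signal`: well-reported drugs whose
#' disproportionality is nonetheless null at every term.
#'
#' @param cases Deduplicated case tibble.
#' @param drug Standardized DRUG tibble.
#' @param reac REAC tibble.
#' @param event_def Multi-PT [event_definition()].
#' @param target_keys Ingredient keys to break down (e.g. the top 50 by
#'   count).
#' @param role_filter,counting_unit Passed to [build_case_rows()].
#' @return A list with `breakdown` (tibble: `ingredient_key`, `pt_name`,
#'   `a`, `ci_low`) and `negative_signal_keys` (character).
#' @export
pt_level_breakdown <- function(cases, drug, reac,
                               event_def = default_event_definition(),
                               target_keys, role_filter = "PS",
                               counting_unit = "case-drug") {
  per_pt <- purrr::map(seq_len(nrow(event_def)), function(i) {
    single <- event_definition(event_def$pt_name[i], event_def$pt_code[i])
    flags <- flag_event_cases(reac, single)
    rows <- build_case_rows(cases, drug, flags,
      reac = reac, role_filter = role_filter,
      counting_unit = counting_unit, event_def = single
    )
    analyze_signals(rows) |>
      tibble::as_tibble() |>
      dplyr::filter(.data$ingredient_key %in% target_keys) |>
      dplyr::transmute(
        ingredient_key = .data$ingredient_key,
        pt_name = event_def$pt_name[i],
        a = .data$a,
        ci_low = .data$ci_low
      )
  })
  breakdown <- dplyr::bind_rows(per_pt) |>
    tidyr::complete(
      ingredient_key = target_keys,
      pt_name = event_def$pt_name,
      fill = list(a = 0, ci_low = NA_real_)
    ) |>
    dplyr::arrange(.data$ingredient_key, .data$pt_name)
  negative <- breakdown |>
    dplyr::group_by(.data$ingredient_key) |>
    dplyr::summarise(
      negative = !any(dplyr::coalesce(.data$ci_low, 0) > 1),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$negative) |>
    dplyr::pull(.data$ingredient_key)
  list(breakdown = breakdown, negative_signal_keys = negative)
}
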