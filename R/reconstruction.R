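#' Invert printed summary statistics to a full 2x2 table
#'
#' Given a drug's printed event-report count `a`, its ROR `r`, its PRR `p`
#' and the total number of event cases `E` in the corpus, the remaining
#' cells of the case/non-case table are determined in closed form:
#' `c = E - a`, `b = a (p - 1) / (r - p)`, `d = r c b / a` (from the
#' identity `p = (a + r b) / (a + b)`). This assumes every event case
#' contributes exactly one primary-suspect key, so `c = E - a`; the
#' assumption is accurate for small-`a` rows, where the reconstructed CI
#' bounds and chi-square agree with printed reference values to well under
#' 0.5%, and degrades as `a` approaches `E`.
#'
#' @param a Number of event reports with the drug (vectorized).
#' @param total_events Total event-case count `E` of the corpus.
#' @param ror Printed reporting odds ratio.
#' @param prr Printed proportional reporting ratio.
#' @return A tibble with columns `a`, `b`, `c`, `d` and `reason`
#'   (`NA` on success; rows with `ror <= prr`, for which no positive
#'   solution exists, carry `NA` cells and an explanatory reason).
#' @examples
#' invert_contingency(815, 32187, 39.96, 39.05)
#' @export
invert_contingency <- function(a, total_events, ror, prr) {
  n <- max(length(a), length(total_events), length(ror), length(prr))
  a <- rep_len(as.numeric(a), n)
  total_events <- rep_len(as.numeric(total_events), n)
  ror <- rep_len(as.numeric(ror), n)
  prr <- rep_len(as.numeric(prr), n)
  ok <- a >= 1 & total_events > a & prr > 1 & ror > prr
  b <- ifelse(ok, a * (prr - 1) / (ror - prr), NA_real_)
  c_ <- ifelse(ok, total_events - a, NA_real_)
  d <- ifelse(ok, ror * c_ * b / a, NA_real_)
  tibble::tibble(
    a = ifelse(ok, a, NA_real_), b = b, c = c_, d = d,
    reason = dplyr::case_when(
      ok ~ NA_character_,
      !(a >= 1) ~ "a must be >= 1",
      !(total_events > a) ~ "total_events must exceed a",
      !(prr > 1) ~ "prr must exceed 1",
      TRUE ~ "no positive solution: ror <= prr"
    )
  )
}

#' Printed reference rows shipped with the package
#'
#' The 50 strongest-signal rows (drug, event-report count, ROR with 95% CI,
#' PRR with chi-square) from a published disproportionality analysis of
#' lactic acidosis and hyperlactatemia in FAERS (2004 Q1 - 2024 Q2;
#' 32,187 event cases), used as the desk-scale oracle for the statistics:
#' inverting each row and recomputing the CI bounds and chi-square must
#' recover the printed values.
#'
#' @return A tibble: `ingredient_key`, `a`, `ror`, `ci_low`, `ci_high`,
#'   `prr`, `chi2`.
#' @export
printed_reference_rows <- function() {
  readr::read_csv(
    system.file("extdata", "printed_reference_rows.csv", package = "faerslahl"),
    col_types = readr::cols(
      ingredient_key = readr::col_character(),
      .default = readr::col_double()
    )
  )
}

#' Check printed rows against their reconstructed tables
#'
#' For each printed row, inverts (a, ROR, PRR, E) to a full table with
#' [invert_contingency()], recomputes the 95% CI bounds and the Pearson
#' chi-square, and reports relative errors against the printed values.
#'
#' Rows whose printed `ror - prr` difference is below `ill_conditioned_gap`
#' are flagged ill-conditioned: the reconstructed `b` cell (and hence the
#' chi-square) is then dominated by printed rounding, so the chi-square
#' comparison is reported but not scored as pass/fail. Likewise, rows where
#' `a` exceeds `large_a_fraction` of the event total are flagged `large_a`:
#' the `c = E - a` single-suspect-per-case assumption distorts the
#' chi-square when `a` is comparable to `c`, so only the CI bounds are
#' scored there. The CI bounds are insensitive to `b` whenever `a` is much
#' smaller than `b`, `c`, `d`, and are checked for every row.
#'
#' @param rows Tibble as returned by [printed_reference_rows()] (columns
#'   `ingredient_key`, `a`, `ror`, `ci_low`, `ci_high`, `prr`, `chi2`).
#' @param total_events Total event-case count `E`.
#' @param tolerance Relative tolerance for pass/fail (default 0.005).
#' @param ill_conditioned_gap Minimum printed `ror - prr` gap for the
#'   chi-square check (default 0.1).
#' @param large_a_fraction Maximum `a / total_events` for the chi-square
#'   check (default 0.2).
#' @return A tibble with the reconstructed statistics, per-column relative
#'   errors (`err_ci_low`, `err_ci_high`, `err_chi2`), `ill_conditioned`,
#'   `large_a`, `invertible` and a `pass` flag.
#' @export
check_printed_rows <- function(rows, total_events = 32187, tolerance = 0.005,
                               ill_conditioned_gap = 0.1,
                               large_a_fraction = 0.2) {
  inv <- invert_contingency(rows$a, total_events, rows$ror, rows$prr)
  rs <- ror_stats(inv$a, inv$b, inv$c, inv$d)
  chi2 <- chi_square_stat(inv$a, inv$b, inv$c, inv$d)
  rel_err <- function(est, printed) abs(est - printed) / printed
  out <- tibble::tibble(
    ingredient_key = rows$ingredient_key,
    a = rows$a,
    invertible = is.na(inv$reason),
    ill_conditioned = (rows$ror - rows$prr) < ill_conditioned_gap,
    large_a = rows$a / total_events > large_a_fraction,
    ci_low_rec = rs$ci_low,
    ci_high_rec = rs$ci_high,
    chi2_rec = chi2,
    err_ci_low = rel_err(rs$ci_low, rows$ci_low),
    err_ci_high = rel_err(rs$ci_high, rows$ci_high),
    err_chi2 = rel_err(chi2, rows$chi2),
    reason = inv$reason
  )
  out$pass <- out$invertible &
    out$err_ci_low <= tolerance &
    out$err_ci_high <= tolerance &
    (out$ill_conditioned | out$large_a | out$err_chi2 <= tolerance)
  out
}
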