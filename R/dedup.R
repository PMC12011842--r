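#' Deduplicate DEMO records by the FDA case rule
#'
#' Spontaneous reports are versioned: the same case (CASEID) can appear in
#' several quarterly packages as follow-up reports with distinct report
#' identifiers (PRIMARYID). Per FDA guidance, the version with the latest
#' FDA receipt date (FDA_DT) is the most complete; on receipt-date ties the
#' highest PRIMARYID wins. Deduplication is performed globally over the
#' concatenation of all quarters, since follow-ups routinely cross quarter
#' boundaries.
#'
#' PRIMARYID comparison is numeric when every identifier in a tie group
#' parses as a number, otherwise lexicographic on zero-padded strings.
#' Records whose FDA_DT does not parse cannot be ordered and are excluded
#' (their count is attached as attribute `n_unparseable_fda_dt`).
#'
#' @param demo A DEMO tibble (rows from one or more quarters) with at least
#'   `primaryid`, `caseid`, `fda_dt`.
#' @return A tibble with one row per distinct `caseid`: the chosen record,
#'   all original columns preserved. Attribute `n_unparseable_fda_dt` holds
#'   the number of excluded rows.
#' @examples
#' demo <- tibble::tibble(
#'   primaryid = c("10011", "10012", "10021"),
#'   caseid = c("1001", "1001", "1002"),
#'   fda_dt = c("20230101", "20230301", "20230215")
#' )
#' dedup_cases(demo)
#' @export
dedup_cases <- function(demo) {
  stopifnot(all(c("primaryid", "caseid", "fda_dt") %in% names(demo)))
  fda_key <- partial_date_key(demo$fda_dt)
  n_bad <- sum(is.na(fda_key))
  keep <- !is.na(fda_key)
  demo <- demo[keep, , drop = FALSE]
  fda_key <- fda_key[keep]

  pid_num <- suppressWarnings(as.numeric(demo$primaryid))
  pid_key <- if (anyNA(pid_num)) {
    stringr::str_pad(demo$primaryid, max(stringr::str_length(demo$primaryid), 0L), pad = "0")
  } else {
    pid_num
  }

  chosen <- demo |>
    dplyr::mutate(.fda_key = fda_key, .pid_key = pid_key) |>
    dplyr::arrange(.data$caseid, .data$.fda_key, .data$.pid_key) |>
    dplyr::group_by(.data$caseid) |>
    dplyr::slice_tail(n = 1L) |>
    dplyr::ungroup() |>
    dplyr::select(-".fda_key", -".pid_key")

  attr(chosen, "n_unparseable_fda_dt") <- n_bad
  chosen
}

#' Remove cases listed in quarterly DELETED files
#'
#' Applied after deduplication, mirroring the published processing sequence:
#' deduplicate first, then drop every case whose identifier appears in the
#' union of all quarters' deletion lists.
#'
#' @param chosen Deduplicated case tibble from [dedup_cases()].
#' @param deleted_caseids Character vector (or set) of deleted case ids,
#'   typically the union of [read_deleted_cases()] over quarters.
#' @return Filtered tibble; attribute `n_deleted` holds the removal count.
#' @export
apply_deletions <- function(chosen, deleted_caseids) {
  deleted_caseids <- unique(as.character(deleted_caseids))
  out <- dplyr::filter(chosen, !(.data$caseid %in% deleted_caseids))
  attr(out, "n_deleted") <- nrow(chosen) - nrow(out)
  attr(out, "n_unparseable_fda_dt") <- attr(chosen, "n_unparseable_fda_dt")
  out
}
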