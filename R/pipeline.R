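#' Pipeline configuration
#'
#' Bundles every knob of an end-to-end run: where the quarterly packages
#' live, how drug names and the event are defined, the counting unit and
#' role filter, the signal thresholds, and where outputs go.
#'
#' @param input_dir Directory holding the quarterly files.
#' @param quarters Character vector of quarter labels to ingest.
#' @param drug_map_path Optional path to a drug map CSV
#'   ([read_drug_map()]).
#' @param event_pt_path Optional path to an event-definition CSV; default
#'   is the packaged three-PT lactic-acidosis set.
#' @param role_filter Drug role codes counted (default `"PS"`).
#' @param counting_unit Counting unit for [build_case_rows()].
#' @param criteria A [signal_criteria()].
#' @param country_field `"occurrence"` or `"reporter"` (see
#'   [build_case_summaries()]).
#' @param top_n Size of the ranked tables (default 50).
#' @param output_dir Optional directory for delimited outputs; `NULL`
#'   keeps results in memory only.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, quarters, drug_map_path = NULL,
                            event_pt_path = NULL, role_filter = "PS",
                            counting_unit = "case-drug",
                            criteria = signal_criteria(),
                            country_field = "occurrence",
                            top_n = 50, output_dir = NULL) {
  config <- list(
    input_dir = input_dir, quarters = quarters,
    drug_map_path = drug_map_path, event_pt_path = event_pt_path,
    role_filter = role_filter, counting_unit = counting_unit,
    criteria = criteria, country_field = country_field,
    top_n = top_n, output_dir = output_dir
  )
  class(config) <- "pipeline_config"
  config
}

#' Run the full analysis pipeline
#'
#' Executes parse, global dedup, deletion-list removal, drug
#' standardization, event flagging, case-row construction,
#' disproportionality analysis and descriptive summaries, keeping a
#' row-count ledger per stage (cases in, unique cases, deleted, retained,
#' event cases). All randomness-free: identical inputs and config give
#' identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `faers_run`: `signals` ([analyze_signals()]
#'   result), `top_by_count`, `top_by_ror`, `pt_breakdown`,
#'   `characteristics`, `yearly_counts`, `onset_bins`, `ledger` (stage row
#'   counts), `event_cases` (per-case summary tibble), `config`.
#' @export
run_faers_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  quarters <- purrr::map(config$quarters, function(q) {
    read_faers_quarter(config$input_dir, q)
  })
  demo <- dplyr::bind_rows(purrr::map(quarters, "demo"))
  drug <- dplyr::bind_rows(purrr::map(quarters, "drug"))
  reac <- dplyr::bind_rows(purrr::map(quarters, "reac"))
  ther <- dplyr::bind_rows(purrr::map(quarters, "ther"))
  outc <- dplyr::bind_rows(purrr::map(quarters, "outc"))
  deleted <- unique(unlist(
    purrr::map(config$quarters, ~ read_deleted_cases(config$input_dir, .x))
  ))

  chosen <- dedup_cases(demo)
  retained <- apply_deletions(chosen, deleted)

  drug_map <- if (!is.null(config$drug_map_path)) {
    read_drug_map(config$drug_map_path)
  }
  event_def <- if (!is.null(config$event_pt_path)) {
    read_event_definition(config$event_pt_path)
  } else {
    default_event_definition()
  }
  drug_std <- standardize_drugs(drug, drug_map)
  flags <- flag_event_cases(reac, event_def)

  rows <- build_case_rows(
    retained, drug_std, flags,
    reac = reac, role_filter = config$role_filter,
    counting_unit = config$counting_unit, event_def = event_def
  )
  signals <- analyze_signals(rows, config$criteria)
  top_by_count <- rank_signals(signals, "case_count", config$top_n)
  top_by_ror <- rank_signals(signals, "ror", config$top_n)
  breakdown <- pt_level_breakdown(
    retained, drug_std, reac, event_def,
    target_keys = top_by_count$ingredient_key,
    role_filter = config$role_filter
  )

  event_ids <- flags$primaryid[flags$is_event]
  event_cases <- dplyr::filter(retained, .data$primaryid %in% event_ids)
  summaries <- build_case_summaries(
    event_cases, outc,
    drug = drug_std, ther = ther,
    country_field = config$country_field
  )
  characteristics <- summarize_cases(summaries)
  yearly <- yearly_counts(summaries)
  bins <- onset_bins(summaries)

  ledger <- tibble::tibble(
    stage = c(
      "demo records in", "malformed lines skipped", "unique cases",
      "unparseable FDA_DT excluded", "cases deleted", "cases retained",
      "event cases", "analysis rows", "event rows", "drugs analyzed"
    ),
    rows = c(
      nrow(demo),
      sum(purrr::map_int(quarters, ~ sum(.x$skipped))),
      nrow(chosen),
      attr(chosen, "n_unparseable_fda_dt"),
      attr(retained, "n_deleted"),
      nrow(retained),
      nrow(event_cases),
      nrow(rows),
      sum(rows$is_event),
      nrow(signals)
    )
  )

  run <- list(
    signals = signals, top_by_count = top_by_count, top_by_ror = top_by_ror,
    pt_breakdown = breakdown, characteristics = characteristics,
    yearly_counts = yearly, onset_bins = bins, ledger = ledger,
    event_cases = summaries, config = config
  )
  class(run) <- "faers_run"
  if (!is.null(config$output_dir)) {
    write_run_outputs(run, config$output_dir)
  }
  run
}

write_run_outputs <- function(run, dir) {
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  readr::write_csv(tibble::as_tibble(run$signals), file.path(dir, "signal_table.csv"))
  readr::write_csv(tibble::as_tibble(run$top_by_count), file.path(dir, "top_by_count.csv"))
  readr::write_csv(tibble::as_tibble(run$top_by_ror), file.path(dir, "top_by_strength.csv"))
  readr::write_csv(run$pt_breakdown$breakdown, file.path(dir, "pt_level.csv"))
  readr::write_csv(run$characteristics, file.path(dir, "characteristics.csv"))
  readr::write_csv(run$yearly_counts, file.path(dir, "yearly_counts.csv"))
  readr::write_csv(run$ledger, file.path(dir, "stage_ledger.csv"))
  cfg_for_hash <- unclass(run$config)
  cfg_for_hash$output_dir <- NULL # same analysis, any destination: same hash
  meta <- list(
    config_hash = rlang::hash(cfg_for_hash),
    package_version = as.character(utils::packageVersion("faerslahl")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    counting_unit = run$config$counting_unit,
    role_filter = run$config$role_filter,
    onset_definition = paste(
      "event date minus earliest day-precise primary-suspect therapy start;",
      "assumption, not asserted by any upstream source"
    )
  )
  jsonlite::write_json(meta, file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.faers_run <- function(x, ...) {
  cat("FAERS-style disproportionality run\n")
  cat(sprintf("  quarters: %s\n", paste(x$config$quarters, collapse = ", ")))
  print(x$ledger, n = Inf)
  g <- generics::glance(x$signals)
  cat(sprintf(
    "  drugs analyzed: %d | ROR signals: %d | PRR signals: %d | both: %d\n",
    g$n_drugs, g$n_ror_signals, g$n_prr_signals, g$n_both_signals
  ))
  invisible(x)
}
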