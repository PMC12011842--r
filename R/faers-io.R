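#' @importFrom rlang .data .env %||%
NULL

# Header-name tolerance tables: FAERS schemas drifted across 2004-2024, so
# columns are located by name through these alias lists, never by position.
# The first alias is the canonical output name.
faers_column_aliases <- list(
  demo = list(
    primaryid = c("primaryid", "isr"),
    caseid = c("caseid", "case"),
    fda_dt = c("fda_dt"),
    event_dt = c("event_dt"),
    age = c("age"),
    age_cod = c("age_cod"),
    sex = c("sex", "gndr_cod"),
    occp_cod = c("occp_cod"),
    reporter_country = c("reporter_country"),
    occr_country = c("occr_country")
  ),
  drug = list(
    primaryid = c("primaryid", "isr"),
    drug_seq = c("drug_seq"),
    role_cod = c("role_cod"),
    drugname = c("drugname"),
    prod_ai = c("prod_ai")
  ),
  reac = list(
    primaryid = c("primaryid", "isr"),
    pt = c("pt"),
    pt_cod = c("pt_cod")
  ),
  ther = list(
    primaryid = c("primaryid", "isr"),
    dsg_drug_seq = c("dsg_drug_seq", "drug_seq"),
    start_dt = c("start_dt"),
    end_dt = c("end_dt")
  ),
  outc = list(
    primaryid = c("primaryid", "isr"),
    outc_cod = c("outc_cod", "outc_code")
  )
)

# Columns that must be present for downstream stages to work at all.
faers_mandatory_columns <- list(
  demo = c("primaryid", "caseid", "fda_dt"),
  drug = c("primaryid", "drug_seq", "role_cod", "drugname"),
  reac = c("primaryid", "pt"),
  ther = c("primaryid", "dsg_drug_seq"),
  outc = c("primaryid", "outc_cod")
)

faers_integer_columns <- c("drug_seq", "dsg_drug_seq", "pt_cod")
faers_numeric_columns <- c("age")

faers_table_file <- function(dir, table, quarter_id) {
  file.path(dir, sprintf("%s_%s.txt", toupper(table), quarter_id))
}

# Split one FAERS line on the dollar delimiter. No quoting or escaping is
# assumed: an embedded "$" changes the field count and the line is treated
# as malformed by the caller.
split_faers_line <- function(lines) {
  stringr::str_split(lines, stringr::fixed("$"))
}

parse_faers_table <- function(path, table) {
  aliases <- faers_column_aliases[[table]]
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!(seq_along(lines) > 1 & lines == "")]
  if (length(lines) == 0L) {
    stop(sprintf("FAERS table file is empty: %s", path), call. = FALSE)
  }
  header <- tolower(stringr::str_trim(split_faers_line(lines[1])[[1]]))
  col_idx <- purrr::map_int(aliases, function(al) {
    hit <- which(header %in% al)
    if (length(hit) == 0L) NA_integer_ else hit[1]
  })
  missing_mandatory <- setdiff(
    faers_mandatory_columns[[table]],
    names(col_idx)[!is.na(col_idx)]
  )
  if (length(missing_mandatory) > 0L) {
    stop(sprintf(
      "FAERS %s header in %s is missing mandatory column(s): %s",
      toupper(table), path, paste(missing_mandatory, collapse = ", ")
    ), call. = FALSE)
  }
  data_lines <- lines[-1]
  fields <- split_faers_line(data_lines)
  ok <- lengths(fields) == length(header)
  n_skipped <- sum(!ok)
  fields <- fields[ok]
  out <- purrr::map(col_idx, function(i) {
    if (is.na(i)) {
      rep(NA_character_, length(fields))
    } else {
      v <- stringr::str_trim(purrr::map_chr(fields, i, .default = NA_character_))
      dplyr::na_if(v, "")
    }
  })
  out <- tibble::as_tibble(out)
  for (col in intersect(names(out), faers_integer_columns)) {
    out[[col]] <- suppressWarnings(as.integer(out[[col]]))
  }
  for (col in intersect(names(out), faers_numeric_columns)) {
    out[[col]] <- suppressWarnings(as.numeric(out[[col]]))
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read one FAERS-style quarterly data package
#'
#' Reads the dollar-delimited DEMO, DRUG, REAC, THER and OUTC tables for one
#' quarter into typed tibbles. Field positions are taken from each file's
#' header line (with a tolerance table for historical column renames), never
#' assumed. Data lines whose field count does not match the header are
#' skipped and counted, never silently dropped.
#'
#' @param dir Directory holding the quarter's table files, named
#'   `DEMO_<quarter>.txt`, `DRUG_<quarter>.txt`, etc.
#' @param quarter_id Quarter label, e.g. `"2023Q1"`.
#' @return A list of class `faers_quarter` with tibbles `demo`, `drug`,
#'   `reac`, `ther`, `outc`, the `quarter_id`, and `skipped`, a named
#'   integer vector of malformed-line counts per table.
#' @seealso [write_faers_quarter()], [read_deleted_cases()]
#' @export
read_faers_quarter <- function(dir, quarter_id) {
  tables <- names(faers_column_aliases)
  paths <- purrr::map_chr(tables, ~ faers_table_file(dir, .x, quarter_id))
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop(sprintf(
      "missing mandatory FAERS file(s) for quarter %s: %s",
      quarter_id, paste(basename(paths[missing]), collapse = ", ")
    ), call. = FALSE)
  }
  parsed <- purrr::map2(paths, tables, parse_faers_table)
  names(parsed) <- tables
  skipped <- purrr::map_int(parsed, ~ attr(.x, "n_skipped"))
  out <- c(parsed, list(quarter_id = quarter_id, skipped = skipped))
  class(out) <- "faers_quarter"
  out
}

#' Read a quarterly DELETED case list
#'
#' Quarterly packages from 2019 onwards ship a list of deleted (invalidated)
#' reports, one case identifier per line. Earlier quarters have no such file;
#' absence is legal and yields an empty set.
#'
#' @param dir Directory holding the quarter's files.
#' @param quarter_id Quarter label, e.g. `"2023Q1"`.
#' @return Character vector of unique, trimmed case identifiers (possibly
#'   empty).
#' @export
read_deleted_cases <- function(dir, quarter_id) {
  path <- faers_table_file(dir, "DELETED", quarter_id)
  if (!file.exists(path)) {
    return(character(0))
  }
  ids <- stringr::str_trim(readr::read_lines(path, progress = FALSE))
  unique(ids[ids != ""])
}

serialize_faers_column <- function(x) {
  out <- as.character(x)
  out[is.na(out)] <- ""
  out
}

#' Write one FAERS-style quarterly data package
#'
#' Serializes a bundle of record tibbles into the dollar-delimited dialect
#' read by [read_faers_quarter()]: a header line naming the columns, then one
#' record per line, missing values as empty fields, day-precise dates as
#' 8-digit strings.
#'
#' @param bundle Named list with tibbles `demo`, `drug`, `reac`, `ther`,
#'   `outc` (columns as produced by [read_faers_quarter()]).
#' @param dir Output directory (created if needed).
#' @param quarter_id Quarter label used in the file names.
#' @return Named character vector of the written file paths, invisibly.
#' @export
write_faers_quarter <- function(bundle, dir, quarter_id) {
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  tables <- names(faers_column_aliases)
  paths <- purrr::map_chr(tables, function(table) {
    tbl <- bundle[[table]]
    stopifnot(is.data.frame(tbl))
    path <- faers_table_file(dir, table, quarter_id)
    cols <- purrr::map(tbl, serialize_faers_column)
    lines <- c(
      paste(names(tbl), collapse = "$"),
      if (nrow(tbl) > 0L) do.call(paste, c(cols, sep = "$"))
    )
    readr::write_lines(lines, path)
    path
  })
  names(paths) <- tables
  invisible(paths)
}

#' Write a quarterly DELETED case list
#'
#' @param caseids Character vector of case identifiers.
#' @param dir Output directory.
#' @param quarter_id Quarter label used in the file name.
#' @return The written path, invisibly.
#' @export
write_deleted_cases <- function(caseids, dir, quarter_id) {
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  path <- faers_table_file(dir, "DELETED", quarter_id)
  readr::write_lines(unique(caseids), path)
  invisible(path)
}
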