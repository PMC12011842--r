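#' Default salt and ester suffixes stripped during drug-name normalization
#'
#' A single trailing token from this list is removed from a verbatim drug
#' name, but only when at least one other token remains and that remainder
#' is not itself just salt vocabulary — so "metformin hydrochloride" becomes
#' "metformin" while the electrolyte product "sodium acetate" is preserved.
#' @return Character vector of suffix tokens.
#' @export
default_salt_suffixes <- function() {
  c(
    "hydrochloride", "hcl", "sodium", "potassium", "calcium", "magnesium",
    "sulfate", "sulphate", "phosphate", "maleate", "mesylate", "besylate",
    "tartrate", "citrate", "acetate", "succinate", "fumarate", "tosylate",
    "bromide", "chloride", "dihydrate", "monohydrate", "anhydrous"
  )
}

#' Normalize a verbatim drug name
#'
#' Trims, collapses internal whitespace, case-folds to lower case, strips
#' trailing periods and a single trailing salt/ester suffix (see
#' [default_salt_suffixes()]).
#'
#' @param verbatim Character vector of verbatim drug names.
#' @param salt_suffixes Suffix tokens to strip; set to `character(0)` to
#'   disable salt stripping.
#' @return Character vector of normalized names (`""` for empty input).
#' @examples
#' normalize_drug_name("  Metformin HYDROCHLORIDE.")
#' normalize_drug_name("Sodium Acetate") # salt-only product, preserved
#' @export
normalize_drug_name <- function(verbatim, salt_suffixes = default_salt_suffixes()) {
  x <- tolower(stringr::str_squish(dplyr::coalesce(as.character(verbatim), "")))
  x <- stringr::str_remove(x, "\\.+$")
  x <- stringr::str_squish(x)
  if (length(salt_suffixes) > 0L) {
    pattern <- sprintf(" (%s)$", paste(salt_suffixes, collapse = "|"))
    stripped <- stringr::str_remove(x, pattern)
    all_salt <- stripped %in% salt_suffixes |
      !stringr::str_detect(stripped, "[a-z]")
    x <- ifelse(all_salt, x, stripped)
  }
  x
}

#' Read a drug-name-to-ingredient mapping table
#'
#' The mapping stands in for a licensed drug dictionary: a two-column
#' delimited file (`verbatim`, `ingredient_key`) supplied by the user. The
#' package ships a small illustrative map in
#' `system.file("extdata", "example_drug_map.csv", package = "faerslahl")`.
#'
#' @param path Path to a CSV file with columns `verbatim` and
#'   `ingredient_key`.
#' @return A tibble with case-folded unique `verbatim` keys.
#' @export
read_drug_map <- function(path) {
  map <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  stopifnot(all(c("verbatim", "ingredient_key") %in% names(map)))
  map <- map |>
    dplyr::mutate(verbatim = tolower(stringr::str_squish(.data$verbatim))) |>
    dplyr::distinct(.data$verbatim, .keep_all = TRUE)
  map
}

split_ingredients <- function(x) {
  stringr::str_split(x, "\\s*/\\s*|\\s*\\+\\s*|\\s+with\\s+")
}

#' Map a normalized drug name to its ingredient-combination key
#'
#' Ingredient keys name the active ingredients of a product: each lower
#' case, sorted alphabetically, joined by "/" (so a combination product is
#' e.g. "lamivudine/stavudine", distinct from either component alone).
#' Names present in the mapping table are replaced by their key; unmapped
#' names pass through with their ingredient parts sorted, and are flagged.
#'
#' @param normalized Character vector from [normalize_drug_name()].
#' @param drug_map Optional mapping tibble from [read_drug_map()].
#' @return A tibble with columns `ingredient_key` and `mapped` (logical:
#'   `FALSE` where the name passed through unmapped).
#' @examples
#' map_drug_key("sitagliptin/metformin")$ingredient_key
#' @export
map_drug_key <- function(normalized, drug_map = NULL) {
  key <- normalized
  mapped <- rep(FALSE, length(key))
  if (!is.null(drug_map) && nrow(drug_map) > 0L) {
    idx <- match(normalized, drug_map$verbatim)
    hit <- !is.na(idx)
    key[hit] <- drug_map$ingredient_key[idx[hit]]
    mapped <- hit
  }
  parts <- split_ingredients(key)
  key <- purrr::map_chr(parts, function(p) {
    p <- stringr::str_squish(p)
    p <- p[p != ""]
    if (length(p) == 0L) "" else paste(sort(p), collapse = "/")
  })
  tibble::tibble(ingredient_key = key, mapped = mapped)
}

#' Standardize a DRUG table to ingredient keys
#'
#' Convenience pipeline verb: normalizes `drugname`, maps it through the
#' drug map, and appends `ingredient_key` and `mapped` columns.
#'
#' @param drug DRUG tibble with a `drugname` column.
#' @param drug_map Optional mapping tibble from [read_drug_map()].
#' @param salt_suffixes Passed to [normalize_drug_name()].
#' @return The input tibble with `ingredient_key` and `mapped` appended.
#' @export
standardize_drugs <- function(drug, drug_map = NULL,
                              salt_suffixes = default_salt_suffixes()) {
  mapped <- map_drug_key(
    normalize_drug_name(drug$drugname, salt_suffixes),
    drug_map
  )
  drug$ingredient_key <- mapped$ingredient_key
  drug$mapped <- mapped$mapped
  drug
}

#' Define the adverse event by a MedDRA preferred-term set
#'
#' The default definition is the three preferred terms of the narrow
#' lactic-acidosis standardised MedDRA query: blood lactic acid increased
#' (10005635), hyperlactacidaemia (10020660) and lactic acidosis (10023676).
#'
#' @param pt_names Character vector of preferred-term names.
#' @param pt_codes Integer vector of MedDRA PT codes, parallel to
#'   `pt_names` (optional, `NA` allowed).
#' @return A tibble of class `event_definition` with columns `pt_code`,
#'   `pt_name`.
#' @export
event_definition <- function(pt_names, pt_codes = rep(NA_integer_, length(pt_names))) {
  stopifnot(length(pt_names) > 0L, length(pt_codes) == length(pt_names))
  def <- tibble::tibble(
    pt_code = as.integer(pt_codes),
    pt_name = as.character(pt_names)
  )
  class(def) <- c("event_definition", class(def))
  def
}

#' @rdname event_definition
#' @export
default_event_definition <- function() {
  read_event_definition(
    system.file("extdata", "lactic_acidosis_pts.csv", package = "faerslahl")
  )
}

#' Read an event definition from a delimited file
#'
#' @param path CSV file with columns `pt_code`, `pt_name`.
#' @return An `event_definition` tibble.
#' @rdname event_definition
#' @export
read_event_definition <- function(path) {
  def <- readr::read_csv(path, col_types = readr::cols(
    pt_code = readr::col_integer(),
    pt_name = readr::col_character()
  ))
  event_definition(def$pt_name, def$pt_code)
}

#' Flag event cases from REAC records
#'
#' A report is an event case iff at least one of its reactions matches the
#' event definition — by PT code when the report carries codes, otherwise by
#' case-insensitive name. A report counts as ONE case no matter how many
#' event PTs it lists; the matched PT subset is retained for PT-level
#' breakdowns (so the per-PT counts can sum to more than the case count).
#'
#' @param reac REAC tibble with `primaryid`, `pt` and optionally `pt_cod`.
#' @param event_def An [event_definition()].
#' @return A tibble with one row per distinct `primaryid` present in
#'   `reac`: `is_event` (logical) and `matched_pts` (list column of matched
#'   canonical PT names, empty where `is_event` is `FALSE`).
#' @export
flag_event_cases <- function(reac, event_def = default_event_definition()) {
  stopifnot(all(c("primaryid", "pt") %in% names(reac)))
  has_code <- "pt_cod" %in% names(reac)
  name_l <- tolower(stringr::str_squish(dplyr::coalesce(reac$pt, "")))
  def_name_l <- tolower(stringr::str_squish(event_def$pt_name))
  idx_by_name <- match(name_l, def_name_l)
  idx <- idx_by_name
  if (has_code) {
    idx_by_code <- match(reac$pt_cod, event_def$pt_code)
    idx <- dplyr::coalesce(idx_by_code, idx_by_name)
  }
  reac |>
    dplyr::mutate(.matched = event_def$pt_name[idx]) |>
    dplyr::group_by(.data$primaryid) |>
    dplyr::summarise(
      is_event = any(!is.na(.data$.matched)),
      matched_pts = list(unique(.data$.matched[!is.na(.data$.matched)])),
      .groups = "drop"
    )
}
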