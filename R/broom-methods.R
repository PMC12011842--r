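#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a signal-analysis result
#'
#' Returns the per-drug statistics as a plain tibble, attributes and class
#' stripped.
#'
#' @param x A `faers_signals` object from [analyze_signals()].
#' @param ... Unused.
#' @return A tibble, one row per ingredient key.
#' @method tidy faers_signals
#' @export
tidy.faers_signals <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- setdiff(class(out), "faers_signals")
  out
}

#' One-row summary of a signal-analysis result
#'
#' @param x A `faers_signals` object from [analyze_signals()].
#' @param ... Unused.
#' @return A one-row tibble: number of drugs analyzed, evaluable tables,
#'   signals under each criterion and under both, and the analysis row
#'   totals.
#' @method glance faers_signals
#' @export
glance.faers_signals <- function(x, ...) {
  tibble::tibble(
    n_drugs = nrow(x),
    n_evaluable = sum(x$evaluable),
    n_ror_signals = sum(x$ror_signal),
    n_prr_signals = sum(x$prr_signal),
    n_both_signals = sum(x$ror_signal & x$prr_signal),
    n_rows = attr(x, "n_rows"),
    n_event_rows = attr(x, "n_event_rows")
  )
}

#' @export
print.faers_signals <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<faers_signals> %d drugs | %d evaluable | %d ROR signals | %d PRR signals\n",
    g$n_drugs, g$n_evaluable, g$n_ror_signals, g$n_prr_signals
  ))
  NextMethod()
}
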