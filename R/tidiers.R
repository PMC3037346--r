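#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a filter development trace
#'
#' @param x A `filter_trace` from [greedy_build()].
#' @param ... Unused.
#' @return The trace tibble: one row per evaluated candidate per step.
#' @export
tidy.filter_trace <- function(x, ...) x$trace

#' One-row summary of a filter development run
#'
#' @inheritParams tidy.filter_trace
#' @return A one-row tibble: number of terms selected, candidates
#'   eliminated, set size, final retrieved count and recall.
#' @export
glance.filter_trace <- function(x, ...) {
  tibble(
    n_terms = nrow(x$strategy),
    n_eliminated = nrow(x$eliminated),
    set_size = x$set_size,
    retrieved = x$final_retrieved,
    recall_pct = x$final_recall_pct,
    tie_break = x$tie_break
  )
}

#' Tidy a recall evaluation
#'
#' @param x A `retrieval_eval` from [recall_eval()].
#' @param ... Unused.
#' @return A tibble of missed record ids (zero rows when recall is 100%).
#' @export
tidy.retrieval_eval <- function(x, ...) {
  tibble(record_id = x$missed_ids, retrieved = FALSE)
}

#' @rdname tidy.retrieval_eval
#' @return For `glance()`: a one-row tibble with `retrieved`, `set_size`,
#'   `recall_pct`, `n_missed`.
#' @export
glance.retrieval_eval <- function(x, ...) {
  tibble(
    retrieved = x$retrieved,
    set_size = x$set_size,
    recall_pct = x$recall_pct,
    n_missed = length(x$missed_ids)
  )
}

#' Tidy a precision screen
#'
#' @param x A `precision_screen` from [precision_screen()].
#' @param ... Unused.
#' @return The per-record screening tibble (`record_id`, `rank`,
#'   `relevant`).
#' @export
tidy.precision_screen <- function(x, ...) x$screening

#' @rdname tidy.precision_screen
#' @return For `glance()`: one row with `screened_n`, `relevant_n`,
#'   `precision_pct`.
#' @export
glance.precision_screen <- function(x, ...) {
  tibble(
    screened_n = x$screened_n,
    relevant_n = x$relevant_n,
    precision_pct = x$precision_pct
  )
}
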