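#' Recall of a strategy in a gold standard set
#'
#' Recall (sensitivity) is the proportion of all relevant references —
#' here, every record of the gold standard corpus — that the strategy
#' retrieves.
#'
#' @param strategy A strategy tibble.
#' @param gold A non-empty corpus tibble of known-relevant records.
#' @return A `retrieval_eval` object with `retrieved`, `set_size`,
#'   `recall_pct` (half-up, one decimal) and `missed_ids`.
#' @export
recall_eval <- function(strategy, gold) {
  gold <- as_corpus(gold)
  if (!nrow(gold)) abort("`gold` corpus is empty")
  ids <- retrieve(gold, strategy)
  structure(
    list(
      retrieved = length(ids),
      set_size = nrow(gold),
      recall_pct = pct1(length(ids), nrow(gold)),
      missed_ids = setdiff(gold$record_id, ids),
      strategy = strategy
    ),
    class = "retrieval_eval"
  )
}

#' @export
print.retrieval_eval <- function(x, ...) {
  cat(sprintf(
    "<retrieval_eval> %d/%d records retrieved (recall %.1f%%); %d missed\n",
    x$retrieved, x$set_size, x$recall_pct, length(x$missed_ids)
  ))
  invisible(x)
}

#' Post-hoc precision screen
#'
#' Precision estimated by human relevance screening of the first `first_n`
#' records a strategy retrieves from a (typically unrestricted) corpus.
#' "First" means corpus order as loaded, standing in for the database's
#' default result ordering; record that ordering alongside the result.
#'
#' @param strategy A strategy tibble.
#' @param corpus The corpus the strategy is run in.
#' @param first_n Number of leading retrievals to screen (e.g. 200).
#' @param labels A data frame with columns `record_id` and `relevant`
#'   (logical or `"yes"/"no"`), covering at least the screened records.
#' @return A `precision_screen` object with `screened_n`, `relevant_n`,
#'   `precision_pct` and the per-record screening tibble.
#' @export
precision_screen <- function(strategy, corpus, first_n, labels) {
  first_n <- assert_scalar_count(first_n, "first_n")
  ids <- retrieve(as_corpus(corpus), strategy)
  if (length(ids) < first_n) {
    abort(sprintf("strategy retrieves only %d records; cannot screen the first %d",
                  length(ids), first_n))
  }
  screened <- ids[seq_len(first_n)]
  labels <- as_tibble(labels)
  if (!all(c("record_id", "relevant") %in% names(labels))) {
    abort("`labels` needs `record_id` and `relevant` columns")
  }
  if (is.character(labels$relevant)) {
    labels$relevant <- tolower(labels$relevant) %in% c("yes", "y", "true", "1")
  }
  pos <- match(screened, labels$record_id)
  if (anyNA(pos)) {
    abort(sprintf(
      "missing relevance labels for retrieved records: %s",
      paste(utils::head(screened[is.na(pos)], 10), collapse = ", ")
    ))
  }
  rel <- labels$relevant[pos]
  structure(
    list(
      screened_n = first_n,
      relevant_n = sum(rel),
      precision_pct = pct1(sum(rel), first_n),
      screening = tibble(record_id = screened, rank = seq_len(first_n), relevant = rel),
      strategy = strategy
    ),
    class = "precision_screen"
  )
}

#' @export
print.precision_screen <- function(x, ...) {
  cat(sprintf(
    "<precision_screen> %d/%d screened records relevant (precision %.1f%%)\n",
    x$relevant_n, x$screened_n, x$precision_pct
  ))
  invisible(x)
}

#' Specificity against an irrelevant-labelled corpus
#'
#' Specificity — irrelevant references correctly *excluded* as a
#' proportion of all irrelevant references — is only computable when a
#' corpus of known-irrelevant records is available; gold standards built
#' purely from relevant references cannot supply one.
#'
#' @param strategy A strategy tibble.
#' @param irrelevant A corpus of known-irrelevant records.
#' @return A one-row tibble with `excluded`, `set_size`, `specificity_pct`.
#' @export
specificity_eval <- function(strategy, irrelevant) {
  irrelevant <- as_corpus(irrelevant)
  if (!nrow(irrelevant)) abort("`irrelevant` corpus is empty")
  hit <- length(retrieve(irrelevant, strategy))
  excl <- nrow(irrelevant) - hit
  tibble(
    excluded = excl,
    set_size = nrow(irrelevant),
    specificity_pct = pct1(excl, nrow(irrelevant))
  )
}

#' MeSH indexing of the records a strategy missed
#'
#' Tallies subject-heading descriptors over the records a recall
#' evaluation failed to retrieve — the standard post-mortem for
#' understanding what a filter's terms do not reach.
#'
#' @param result A [recall_eval()] result.
#' @param gold The same gold corpus the evaluation ran on.
#' @return A tibble of (`descriptor`, `n`) in descending frequency
#'   (ties alphabetical); zero rows when nothing was missed.
#' @export
missed_report <- function(result, gold) {
  gold <- as_corpus(gold)
  missed <- gold[gold$record_id %in% result$missed_ids, , drop = FALSE]
  descs <- unlist(lapply(corpus_descriptors(missed), function(d) {
    d[!duplicated(norm_descriptor(d))]
  }), use.names = FALSE)
  if (!length(descs)) return(tibble(descriptor = character(), n = integer()))
  key <- norm_descriptor(descs)
  first_form <- tapply(descs, key, function(x) x[[1]])
  counts <- table(key)
  out <- tibble(
    descriptor = as.character(first_form[names(counts)]),
    n = as.integer(counts)
  )
  dplyr::arrange(out, dplyr::desc(.data$n), tolower(.data$descriptor))
}

#' Attribute an irrelevant set's retrievals to filter terms
#'
#' For a corpus of irrelevant records that a strategy nevertheless
#' retrieved, reports how many records each term matches and each term's
#' *unique contribution* — records no other term of the strategy matches.
#' A term whose unique contribution is small can be removed with little
#' effect on what the filter drags in (though also on what it catches).
#'
#' @param strategy A strategy tibble.
#' @param irrelevant A corpus in which every record is retrieved by
#'   `strategy` (checked).
#' @return A tibble of (`term`, `scope`, `matched`, `unique_contribution`)
#'   in strategy order.
#' @export
false_positive_attribution <- function(strategy, irrelevant) {
  irrelevant <- as_corpus(irrelevant)
  idx <- corpus_index(irrelevant)
  M <- vapply(seq_len(nrow(strategy)), function(i) {
    match_with_index(idx, strategy$text[[i]], strategy$scope[[i]])
  }, logical(nrow(irrelevant)))
  M <- matrix(M, nrow = nrow(irrelevant))
  unretrieved <- !apply(M, 1, any)
  if (any(unretrieved)) {
    abort(sprintf(
      "records not retrieved by the strategy: %s",
      paste(utils::head(irrelevant$record_id[unretrieved], 10), collapse = ", ")
    ))
  }
  nmatch <- rowSums(M)
  tibble(
    term = strategy$text,
    scope = strategy$scope,
    matched = as.integer(colSums(M)),
    unique_contribution = as.integer(colSums(M & nmatch == 1L))
  )
}
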