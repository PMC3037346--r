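#' Bundled stopword list
#'
#' A standard English stopword list shipped with the package, used when
#' tokenising titles and abstracts. Override by passing your own character
#' vector (or a file read with `readLines()`) to the frequency functions.
#'
#' @return Character vector of lowercase stopwords.
#' @export
default_stopwords <- function() {
  readLines(system.file("extdata", "stopwords_en.txt", package = "hedgeR"),
            encoding = "UTF-8")
}

#' Bundled MeSH exclusion list
#'
#' MeSH descriptors not semantically associated with a clinical topic —
#' check tags and descriptors for gender, age group, species and study
#' design — that are filtered out of subject-heading frequency analysis.
#' Editable: pass any character vector of descriptors instead.
#'
#' @return Character vector of descriptors (matched case-insensitively).
#' @export
default_mesh_exclusions <- function() {
  readLines(system.file("extdata", "mesh_exclusions.txt", package = "hedgeR"),
            encoding = "UTF-8")
}

#' Curated heart failure textword/phrase candidates
#'
#' The curated list of heart failure textwords and phrases used as the
#' candidate set for filter development (single words and meaningful
#' phrases such as "left ventricular ejection fraction"). Provided as the
#' worked override for [phrase_candidates()]'s curated route.
#'
#' @return Character vector of lowercase terms.
#' @export
hf_phrase_list <- function() {
  readLines(system.file("extdata", "hf_phrases.txt", package = "hedgeR"),
            encoding = "UTF-8")
}

#' Record-occurrence cutoff specification
#'
#' Candidate terms qualify for filter development only if they retrieve at
#' least `fraction` of the term identification set. The integer threshold
#' is `round(fraction * set_size)` half-up; for the conventional 15% on an
#' 88-record set this is n >= 13. (13/88 is 14.8%, so the stated
#' percentage and the integer threshold disagree slightly; the count
#' threshold governs.)
#'
#' @param fraction Proportion of the set a term must retrieve (default 0.15).
#' @param set_size Size of the term identification set.
#' @return A `cutoff_spec` list with `fraction`, `set_size`, `min_count`.
#' @export
cutoff_spec <- function(fraction = 0.15, set_size) {
  set_size <- assert_scalar_count(set_size, "set_size")
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1) {
    abort("`fraction` must be a proportion in [0, 1]")
  }
  structure(
    list(
      fraction = fraction,
      set_size = set_size,
      min_count = as.integer(round_half_up(fraction * set_size))
    ),
    class = "cutoff_spec"
  )
}

candidate_tbl <- function(term, scope, record_occurrence, set_size, extra = NULL) {
  out <- tibble(
    term = term,
    scope = scope,
    record_occurrence = as.integer(record_occurrence),
    occurrence_pct = pct1(record_occurrence, set_size),
    set_size = as.integer(set_size)
  )
  if (!is.null(extra)) out <- dplyr::bind_cols(out, extra)
  out
}

#' MeSH descriptor frequency analysis
#'
#' Counts, for every distinct subject-heading descriptor in the corpus,
#' the number of distinct records indexed with it (its *record
#' occurrence*). Subheadings and the major-topic flag are ignored; a
#' descriptor appearing twice on one record (with different subheadings)
#' counts once. Descriptors on the exclusion list are dropped
#' (case-insensitive match). Ranked by record occurrence descending, ties
#' alphabetical.
#'
#' @param corpus A non-empty corpus tibble.
#' @param exclusions Character vector of descriptors to exclude; defaults
#'   to [default_mesh_exclusions()].
#' @return A candidate tibble with columns `term` (descriptor as first
#'   seen), `scope` (`"sh"`), `record_occurrence`, `occurrence_pct`
#'   (half-up, one decimal, of the corpus size) and `set_size`.
#' @export
mesh_frequency <- function(corpus, exclusions = default_mesh_exclusions()) {
  corpus <- as_corpus(corpus)
  n <- nrow(corpus)
  if (n == 0L) abort("cannot run frequency analysis on an empty corpus")
  excl <- norm_descriptor(exclusions)
  per_record <- lapply(corpus_descriptors(corpus), function(d) {
    d <- d[!(norm_descriptor(d) %in% excl)]
    d[!duplicated(norm_descriptor(d))]
  })
  all <- unlist(per_record, use.names = FALSE)
  if (!length(all)) {
    return(candidate_tbl(character(), character(), integer(), n))
  }
  key <- norm_descriptor(all)
  first_form <- tapply(all, key, function(x) x[[1]])
  counts <- table(key)
  out <- candidate_tbl(
    term = as.character(first_form[names(counts)]),
    scope = "sh",
    record_occurrence = as.integer(counts),
    set_size = n
  )
  dplyr::arrange(out, dplyr::desc(.data$record_occurrence), tolower(.data$term))
}

#' Single-textword frequency analysis
#'
#' Tokenises titles and abstracts (lowercase; split on any character that
#' is not a letter, digit or internal hyphen; no stemming, no
#' truncation), drops stopwords and all-digit tokens, and ranks the
#' remaining words by total frequency — the concordance ranking. Each
#' word also carries its record occurrence, computed through the query
#' engine's `.mp.` matching so that `record_occurrence` always equals
#' `length(retrieve(corpus, search_strategy(term)))`.
#'
#' @param corpus A non-empty corpus tibble.
#' @param stopwords Character vector; defaults to [default_stopwords()].
#' @return A candidate tibble (scope `"mp"`) with an extra
#'   `total_frequency` column, ranked by total frequency descending, ties
#'   alphabetical.
#' @export
textword_frequency <- function(corpus, stopwords = default_stopwords()) {
  corpus <- as_corpus(corpus)
  n <- nrow(corpus)
  if (n == 0L) abort("cannot run frequency analysis on an empty corpus")
  stop_set <- tolower(stopwords)
  text_toks <- purrr::map2(tokenize(corpus$title), tokenize(corpus$abstract), c)
  keep <- function(t) t[!(t %in% stop_set) & !grepl("^[0-9]+$", t)]
  text_toks <- lapply(text_toks, keep)
  freq <- table(unlist(text_toks, use.names = FALSE))
  if (!length(freq)) {
    return(candidate_tbl(character(), character(), integer(), n,
                         extra = tibble(total_frequency = integer())))
  }
  # record occurrence under .mp. semantics: title/abstract or
  # subject-heading words
  mp_sets <- purrr::map2(
    text_toks,
    lapply(corpus_descriptors(corpus), function(d) {
      unlist(tokenize(d), use.names = FALSE)
    }),
    function(a, b) unique(c(a, keep(b)))
  )
  occ <- table(unlist(mp_sets, use.names = FALSE))
  words <- names(freq)
  out <- candidate_tbl(
    term = words,
    scope = "mp",
    record_occurrence = as.integer(occ[words]),
    set_size = n,
    extra = tibble(total_frequency = as.integer(freq))
  )
  dplyr::arrange(out, dplyr::desc(.data$total_frequency), .data$term)
}

#' Phrase candidate discovery
#'
#' Proposes contiguous n-grams (length 2 to `max_len`) from titles and
#' abstracts as candidate phrases. An n-gram qualifies if it contains at
#' least one of the `top_k_words` most frequent non-stop words and does
#' not begin or end with a stopword (stopword-boundary trimming).
#' Candidates are ranked by record occurrence (via `.mp.` matching).
#'
#' The n-gram proposal stands in for manual concordance review:
#' judging which n-grams are *meaningful* phrases (independent concepts)
#' requires a human. Supply that judgement through `curated`, a character
#' vector of terms/phrases; when given, exactly those are scored and
#' ranked, and discovery is skipped.
#'
#' @param corpus A corpus tibble.
#' @param top_k_words Number of top frequency-ranked words whose contexts
#'   are scanned (default 110).
#' @param max_len Maximum phrase length in words (2-6, default 4).
#' @param stopwords Character vector; defaults to [default_stopwords()].
#' @param curated Optional curated term list overriding discovery (e.g.
#'   [hf_phrase_list()]).
#' @param min_records Discovery only: drop n-grams seen in fewer than this
#'   many records (default 2).
#' @return A candidate tibble (scope `"mp"`).
#' @export
phrase_candidates <- function(corpus, top_k_words = 110, max_len = 4,
                              stopwords = default_stopwords(),
                              curated = NULL, min_records = 2) {
  corpus <- as_corpus(corpus)
  n <- nrow(corpus)
  if (!is.null(curated)) {
    idx <- corpus_index(corpus)
    occ <- vapply(curated, function(p) sum(match_with_index(idx, p, "mp")), integer(1))
    out <- candidate_tbl(as.character(curated), "mp", occ, n)
    return(dplyr::arrange(out, dplyr::desc(.data$record_occurrence), .data$term))
  }
  if (max_len < 2 || max_len > 6) abort("`max_len` must be in 2..6")
  if (top_k_words < 1) abort("`top_k_words` must be >= 1")
  stop_set <- tolower(stopwords)
  top_words <- utils::head(textword_frequency(corpus, stopwords)$term, top_k_words)
  field_toks <- c(tokenize(corpus$title), tokenize(corpus$abstract))
  field_rec <- rep(seq_len(n), 2L)
  seen <- list()
  for (f in seq_along(field_toks)) {
    toks <- field_toks[[f]]
    if (length(toks) < 2L) next
    for (len in 2:min(max_len, length(toks))) {
      for (s in seq_len(length(toks) - len + 1L)) {
        g <- toks[s:(s + len - 1L)]
        if (g[[1]] %in% stop_set || g[[len]] %in% stop_set) next
        if (!any(g %in% top_words)) next
        key <- paste(g, collapse = " ")
        seen[[key]] <- c(seen[[key]], field_rec[[f]])
      }
    }
  }
  if (!length(seen)) return(candidate_tbl(character(), character(), integer(), n))
  # score proposals with the query engine's .mp. matching so record
  # occurrence is exactly what the term would retrieve
  idx <- corpus_index(corpus)
  occ <- vapply(names(seen), function(p) sum(match_with_index(idx, p, "mp")), integer(1))
  keep <- occ >= min_records
  out <- candidate_tbl(names(seen)[keep], "mp", unname(occ[keep]), n)
  dplyr::arrange(out, dplyr::desc(.data$record_occurrence), .data$term)
}

#' Apply the record-occurrence cutoff to a candidate list
#'
#' Keeps candidates whose record occurrence meets the cutoff's integer
#' threshold, preserving their order.
#'
#' @param candidates A candidate tibble (any source).
#' @param cutoff A [cutoff_spec()].
#' @return The filtered candidate tibble.
#' @export
apply_cutoff <- function(candidates, cutoff) {
  if (!inherits(cutoff, "cutoff_spec")) abort("`cutoff` must be a cutoff_spec()")
  dplyr::filter(candidates, .data$record_occurrence >= cutoff$min_count)
}
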