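#' Construct a search strategy
#'
#' A strategy is an ordered tibble of unique search terms combined by OR.
#' Each term has a `scope` mirroring the OvidSP field suffix it would be
#' entered with:
#'
#' * `"mp"` (multi-purpose): matches when the term's token sequence occurs
#'   contiguously, at word boundaries and case-insensitively, in the
#'   title, the abstract, or the word sequence of any subject-heading
#'   descriptor.
#' * `"sh"` (subject heading): matches when the term equals a record's
#'   MeSH descriptor exactly (case-insensitive; subheadings and the
#'   major-topic flag are ignored; no tree explosion).
#'
#' @param text Character vector of term texts.
#' @param scope Character vector (recycled) of `"mp"` or `"sh"`.
#' @param label Optional per-term labels (e.g. `T1`, `T2(a)`); defaults to
#'   `T1..Tn`.
#' @return A strategy tibble with columns `label`, `text`, `scope`.
#' @examples
#' search_strategy(c("heart failure", "ventricular dysfunction, left"),
#'                 scope = c("mp", "sh"))
#' @export
search_strategy <- function(text, scope = "mp", label = NULL) {
  if (!length(text)) {
    return(tibble(label = character(), text = character(), scope = character()))
  }
  scope <- rep_len(scope, length(text))
  if (!all(scope %in% c("mp", "sh"))) abort('`scope` must be "mp" or "sh"')
  if (any(!nzchar(text))) abort("term text must be non-empty")
  if (is.null(label)) label <- paste0("T", seq_along(text))
  out <- tibble(label = label, text = as.character(text), scope = scope)
  if (anyDuplicated(paste(tolower(out$text), out$scope))) {
    abort("strategy terms must be unique (text + scope)")
  }
  out
}

#' The published four-term heart failure filter
#'
#' The validated OvidSP Medline filter: `heart failure.mp. OR ventricular
#' dysfunction, left.sh. OR cardiomyopathy.mp. OR left ventricular
#' ejection fraction.mp.`
#'
#' @return A strategy tibble.
#' @export
hf_filter <- function() {
  search_strategy(
    c(
      "heart failure",
      "ventricular dysfunction, left",
      "cardiomyopathy",
      "left ventricular ejection fraction"
    ),
    scope = c("mp", "sh", "mp", "mp")
  )
}

# Per-corpus index of padded token strings: title, abstract, one string
# per MeSH descriptor, plus normalised descriptors for .sh. equality.
corpus_index <- function(corpus) {
  descs <- corpus_descriptors(corpus)
  list(
    title = pad_tokens(corpus$title),
    abstract = pad_tokens(corpus$abstract),
    mesh_tokens = lapply(descs, function(d) if (length(d)) pad_tokens(d) else character()),
    mesh_norm = lapply(descs, norm_descriptor)
  )
}

match_with_index <- function(idx, text, scope) {
  if (scope == "sh") {
    key <- norm_descriptor(text)
    return(vapply(idx$mesh_norm, function(d) key %in% d, logical(1)))
  }
  key <- term_key(text) # " heart failure "
  hit <- stringr::str_detect(idx$title, stringr::fixed(key)) |
    stringr::str_detect(idx$abstract, stringr::fixed(key))
  need <- which(!hit)
  if (length(need)) {
    hit[need] <- vapply(idx$mesh_tokens[need], function(d) {
      any(stringr::str_detect(d, stringr::fixed(key)))
    }, logical(1))
  }
  hit
}

#' Match a search term against every record of a corpus
#'
#' Implements the field semantics described in [search_strategy()].
#' Matching is deterministic, case-insensitive and punctuation-insensitive
#' (`"ventricular dysfunction, left"` matches `"Ventricular Dysfunction,
#' Left"`).
#'
#' @param corpus A corpus tibble.
#' @param text Term text.
#' @param scope `"mp"` or `"sh"`.
#' @return A logical vector, one element per record.
#' @export
match_records <- function(corpus, text, scope = c("mp", "sh")) {
  scope <- match.arg(scope)
  corpus <- as_corpus(corpus)
  match_with_index(corpus_index(corpus), text, scope)
}

#' Retrieve records matching any term of a strategy
#'
#' OR combination: the retrieved set is the union over the strategy's
#' terms of their per-term match sets.
#'
#' @param corpus A corpus tibble.
#' @param strategy A strategy tibble (see [search_strategy()]).
#' @return Character vector of matching `record_id`s, in corpus order;
#'   empty for an empty strategy.
#' @export
retrieve <- function(corpus, strategy) {
  corpus <- as_corpus(corpus)
  if (!nrow(strategy)) return(character())
  idx <- corpus_index(corpus)
  hit <- rep(FALSE, nrow(corpus))
  for (i in seq_len(nrow(strategy))) {
    hit <- hit | match_with_index(idx, strategy$text[[i]], strategy$scope[[i]])
  }
  corpus$record_id[hit]
}

#' Render a strategy in Ovid syntax
#'
#' One numbered line per term with its `.mp.` or `.sh.` suffix, followed
#' by a final `Or/1-N` combination line. A single-term strategy renders
#' without a combine line (Ovid has no `Or/1-1` idiom). Term text is
#' lowercased, as Ovid search histories print it.
#'
#' @param strategy A non-empty strategy tibble.
#' @return A single string with embedded newlines.
#' @examples
#' cat(render_ovid(hf_filter()))
#' @export
render_ovid <- function(strategy) {
  n <- nrow(strategy)
  if (!n) abort("cannot render an empty strategy")
  lines <- sprintf("%d %s.%s.", seq_len(n), tolower(strategy$text), strategy$scope)
  if (n > 1L) lines <- c(lines, sprintf("%d Or/1-%d", n + 1L, n))
  paste(lines, collapse = "\n")
}

#' Parse an Ovid-style numbered strategy
#'
#' Inverse of [render_ovid()]. Accepts tab- or space-separated line
#' numbers and ignores a trailing `Or/1-N` line.
#'
#' @param text A single string or character vector of lines.
#' @return A strategy tibble.
#' @export
parse_ovid <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  terms <- character()
  scopes <- character()
  for (ln in lines) {
    body <- trimws(sub("^\\d+[\\t ]*", "", ln))
    if (grepl("^or/\\d+-\\d+$", tolower(body))) next
    m <- regmatches(body, regexec("^(.*)\\.(mp|sh)\\.?$", body, ignore.case = TRUE))[[1]]
    if (!length(m)) {
      abort(sprintf("cannot parse Ovid strategy line (unknown suffix?): %s", ln))
    }
    terms <- c(terms, trimws(m[[2]]))
    scopes <- c(scopes, tolower(m[[3]]))
  }
  search_strategy(terms, scopes)
}
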