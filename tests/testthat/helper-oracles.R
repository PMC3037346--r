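# Independent reference implementations used as oracles. Deliberately
# written with plain loops and base string handling, not via the
# package's matching code.

oracle_tokens <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9-]+", " ", x)
  toks <- strsplit(trimws(x), " +")[[1]]
  toks <- gsub("^-+|-+$", "", toks)
  toks[nzchar(toks)]
}

oracle_contains_seq <- function(hay, needle) {
  lh <- length(hay)
  ln <- length(needle)
  if (ln == 0L || lh < ln) return(FALSE)
  for (s in seq_len(lh - ln + 1L)) {
    if (all(hay[s:(s + ln - 1L)] == needle)) return(TRUE)
  }
  FALSE
}

oracle_match_record <- function(rec, text, scope) {
  if (scope == "sh") {
    key <- tolower(gsub(" +", " ", trimws(text)))
    descs <- tolower(gsub(" +", " ", trimws(rec$mesh[[1]]$descriptor)))
    return(key %in% descs)
  }
  needle <- oracle_tokens(text)
  if (oracle_contains_seq(oracle_tokens(rec$title), needle)) return(TRUE)
  if (oracle_contains_seq(oracle_tokens(rec$abstract), needle)) return(TRUE)
  for (d in rec$mesh[[1]]$descriptor) {
    if (oracle_contains_seq(oracle_tokens(d), needle)) return(TRUE)
  }
  FALSE
}

oracle_retrieve <- function(corpus, strategy) {
  hit <- rep(FALSE, nrow(corpus))
  for (i in seq_len(nrow(corpus))) {
    rec <- corpus[i, ]
    for (j in seq_len(nrow(strategy))) {
      if (oracle_match_record(rec, strategy$text[[j]], strategy$scope[[j]])) {
        hit[[i]] <- TRUE
        break
      }
    }
  }
  corpus$record_id[hit]
}

# Exhaustive greedy without elimination: at each step evaluate every
# candidate not yet selected and take the best count (ties by
# lowercase term text then scope, the default policy).
oracle_greedy <- function(candidates, corpus) {
  hits <- lapply(seq_len(nrow(candidates)), function(i) {
    vapply(seq_len(nrow(corpus)), function(r) {
      oracle_match_record(corpus[r, ], candidates$term[[i]], candidates$scope[[i]])
    }, logical(1))
  })
  remaining <- seq_len(nrow(candidates))
  base <- rep(FALSE, nrow(corpus))
  picks <- integer()
  counts <- integer()
  repeat {
    if (!length(remaining)) break
    cnt <- vapply(remaining, function(i) sum(base | hits[[i]]), integer(1))
    if (max(cnt) <= sum(base)) break
    best <- remaining[cnt == max(cnt)]
    best <- best[order(tolower(candidates$term[best]), candidates$scope[best])][[1]]
    picks <- c(picks, best)
    counts <- c(counts, max(cnt))
    base <- base | hits[[best]]
    remaining <- setdiff(remaining, best)
  }
  list(picks = picks, counts = counts, final = sum(base))
}
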