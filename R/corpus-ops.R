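#' Merge corpora, deduplicating by record id
#'
#' Assembles a gold standard from several tagged sub-corpora (e.g. one per
#' source guideline). Records are concatenated in input order; for records
#' sharing a `record_id` the first occurrence is kept and its
#' `source_tags` become the union of the tags carried by all duplicates —
#' the "tag transferral" rule, so provenance survives deduplication.
#'
#' @param corpora A list of corpus tibbles (each internally unique), or a
#'   single corpus.
#' @return One deduplicated corpus tibble.
#' @examples
#' a <- bib_record("1", "Alpha", source_tags = "guideline A")
#' b <- bib_record("1", "Alpha", source_tags = "guideline B")
#' merge_corpora(list(a, b))$source_tags[[1]]
#' @export
merge_corpora <- function(corpora) {
  if (is.data.frame(corpora)) corpora <- list(corpora)
  corpora <- purrr::map(corpora, as_corpus)
  all <- dplyr::bind_rows(corpora)
  if (!nrow(all)) return(bind_records(list()))
  tag_union <- lapply(
    split(all$source_tags, factor(all$record_id, levels = unique(all$record_id))),
    function(tags) unique(unlist(tags, use.names = FALSE))
  )
  kept <- all[!duplicated(all$record_id), , drop = FALSE]
  kept$source_tags <- unname(tag_union[kept$record_id])
  validate_corpus(kept)
}

#' Split a corpus by abstract presence
#'
#' Gold-standard construction excludes records without abstracts, since
#' term identification needs title *and* abstract text. This is a corpus
#' policy, applied once, after parsing.
#'
#' @param corpus A corpus tibble.
#' @return A list with corpus tibbles `kept` (non-empty abstract) and
#'   `excluded` (empty abstract); together they partition the input.
#' @export
require_abstract <- function(corpus) {
  corpus <- as_corpus(corpus)
  has <- nzchar(trimws(corpus$abstract))
  list(kept = corpus[has, , drop = FALSE], excluded = corpus[!has, , drop = FALSE])
}

#' Specify a three-way random split
#'
#' @param fractions Three non-negative proportions (term identification,
#'   filter development, filter validation) summing to 1. Default
#'   `c(0.10, 0.45, 0.45)`, the conventional design for filter studies.
#' @param seed Integer seed; recorded in the split manifest so set
#'   membership is reproducible.
#' @return A `split_spec` list.
#' @export
split_spec <- function(fractions = c(0.10, 0.45, 0.45), seed = 1L) {
  if (length(fractions) != 3L || any(fractions < 0)) {
    abort("`fractions` must be three non-negative proportions")
  }
  if (abs(sum(fractions) - 1) > 1e-9) abort("`fractions` must sum to 1")
  structure(
    list(fractions = as.numeric(fractions), seed = as.integer(seed)),
    class = "split_spec"
  )
}

#' Randomly partition a corpus into term-identification, development and
#' validation sets
#'
#' The term identification set gets `round(f1 * N)` records (half-up, so
#' 876 x 0.10 = 87.6 gives 88); the remainder is halved between
#' development and validation, any odd record going to development.
#' Assignment is a seeded uniform random permutation followed by prefix
#' slicing, so sizes depend only on `N` and the fractions while
#' membership depends only on the seed.
#'
#' @param corpus A non-empty corpus tibble.
#' @param spec A [split_spec()].
#' @return A list of corpus tibbles `term_id`, `development`, `validation`
#'   (a partition of the input, each in original corpus order), plus
#'   `manifest`, a tibble of (`record_id`, `set`, `seed`) suitable for
#'   writing as a plain-text table.
#' @export
split_corpus <- function(corpus, spec = split_spec()) {
  corpus <- as_corpus(corpus)
  n <- nrow(corpus)
  if (n == 0L) abort("cannot split an empty corpus")
  sizes <- split_sizes(n, spec$fractions)
  if (any(sizes == 0L)) {
    abort(sprintf(
      "split of %d records by (%s) yields an empty set", n,
      paste(spec$fractions, collapse = ", ")
    ))
  }
  perm <- withr::with_seed(spec$seed, sample.int(n))
  set <- rep(c("term_id", "development", "validation"), times = sizes)
  assignment <- set[order(perm)] # record i's set
  out <- lapply(c("term_id", "development", "validation"), function(s) {
    corpus[assignment == s, , drop = FALSE]
  })
  names(out) <- c("term_id", "development", "validation")
  out$manifest <- tibble(
    record_id = corpus$record_id,
    set = assignment,
    seed = spec$seed
  )
  out
}

# Half-up rounding for the first fraction; remainder halved with any odd
# record to the development set.
split_sizes <- function(n, fractions) {
  n1 <- as.integer(round_half_up(fractions[[1]] * n))
  rest <- n - n1
  w <- fractions[2:3]
  if (sum(w) <= 0) {
    n2 <- rest
    n3 <- 0L
  } else {
    n3 <- as.integer(floor(rest * w[[2]] / sum(w)))
    n2 <- rest - n3
  }
  c(term_id = n1, development = n2, validation = n3)
}
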