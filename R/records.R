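#' Construct a MeSH heading
#'
#' A MeSH heading is stored in parsed form: the bare descriptor, any
#' subheadings as a character vector, and the major-topic flag. The
#' major-topic asterisk and `/subheading` suffixes that MEDLINE exports
#' embed in the `MH` line are never kept inside the descriptor string,
#' because term frequency analysis and subject-heading retrieval both
#' operate on the bare main heading.
#'
#' @param descriptor Bare MeSH descriptor, e.g. `"Heart Failure"`. Must be
#'   non-empty, with no leading `*` and no `/`.
#' @param subheadings Character vector of subheadings (possibly empty).
#' @param major Logical major-topic flag.
#' @return A one-row tibble with columns `descriptor`, `subheadings`
#'   (list-column), `major`.
#' @examples
#' mesh_heading("Heart Failure", c("drug therapy"), major = TRUE)
#' @export
mesh_heading <- function(descriptor, subheadings = character(), major = FALSE) {
  validate_descriptor(descriptor)
  tibble(
    descriptor = descriptor,
    subheadings = list(as.character(subheadings)),
    major = isTRUE(major)
  )
}

validate_descriptor <- function(descriptor) {
  if (!is.character(descriptor) || length(descriptor) != 1L ||
      is.na(descriptor) || !nzchar(descriptor)) {
    abort("MeSH descriptor must be a single non-empty string")
  }
  if (startsWith(descriptor, "*")) {
    abort(sprintf("MeSH descriptor %s must not carry a leading '*' (parse the major flag out)", descriptor))
  }
  if (grepl("/", descriptor, fixed = TRUE)) {
    abort(sprintf("MeSH descriptor %s must not contain '/' (parse subheadings out)", descriptor))
  }
  invisible(descriptor)
}

# Zero-row mesh table with the canonical schema.
empty_mesh <- function() {
  tibble(descriptor = character(), subheadings = list(), major = logical())
}

#' Construct a single bibliographic record
#'
#' @param record_id Unique identifier (e.g. a PMID), non-empty.
#' @param title Record title, non-empty.
#' @param abstract Abstract text; `""` when the record has none. Records
#'   without abstracts are representable — excluding them is a corpus-level
#'   policy applied by [require_abstract()], not a parsing rule.
#' @param mesh A mesh tibble as built by [mesh_heading()] (rows may be
#'   bound together), or `NULL` for none.
#' @param pub_types Character vector of publication types.
#' @param source_tags Character vector of provenance tags (e.g. the name of
#'   the parent guideline a reference was extracted from).
#' @param year Publication year or `NA`.
#' @return A one-row corpus tibble (see [as_corpus()]).
#' @examples
#' bib_record("101", "Chronic heart failure management",
#'   abstract = "A cohort study.",
#'   mesh = mesh_heading("Heart Failure", "therapy", major = TRUE)
#' )
#' @export
bib_record <- function(record_id, title, abstract = "", mesh = NULL,
                       pub_types = character(), source_tags = character(),
                       year = NA_integer_) {
  as_corpus(tibble(
    record_id = as.character(record_id),
    title = title,
    abstract = abstract,
    mesh = list(if (is.null(mesh)) empty_mesh() else mesh),
    pub_types = list(as.character(pub_types)),
    source_tags = list(as.character(source_tags)),
    year = as.integer(year)
  ))
}

#' Coerce a data frame to a corpus tibble
#'
#' A corpus is an ordered tibble of bibliographic records, one row per
#' record, with columns `record_id`, `title`, `abstract`, `mesh`
#' (list-column of mesh tibbles), `pub_types`, `source_tags` (list-columns
#' of character vectors) and `year`. Missing optional columns are filled
#' with empty defaults. `record_id` values must be unique and titles
#' non-empty.
#'
#' @param x A data frame with at least `record_id` and `title` columns.
#' @return A validated corpus tibble.
#' @export
as_corpus <- function(x) {
  x <- as_tibble(x)
  if (!all(c("record_id", "title") %in% names(x))) {
    abort("a corpus needs `record_id` and `title` columns")
  }
  n <- nrow(x)
  x$record_id <- as.character(x$record_id)
  if ("abstract" %in% names(x)) {
    x$abstract <- dplyr::coalesce(as.character(x$abstract), "")
  } else {
    x$abstract <- character(n)
  }
  if (!"mesh" %in% names(x)) x$mesh <- replicate(n, empty_mesh(), simplify = FALSE)
  if (!"pub_types" %in% names(x)) x$pub_types <- replicate(n, character(), simplify = FALSE)
  if (!"source_tags" %in% names(x)) x$source_tags <- replicate(n, character(), simplify = FALSE)
  if (!"year" %in% names(x)) x$year <- NA_integer_
  x <- x[, c("record_id", "title", "abstract", "mesh", "pub_types", "source_tags", "year")]
  validate_corpus(x)
}

validate_corpus <- function(x) {
  if (anyNA(x$record_id) || any(!nzchar(x$record_id))) {
    abort("every record needs a non-empty `record_id`")
  }
  if (anyDuplicated(x$record_id)) {
    dup <- unique(x$record_id[duplicated(x$record_id)])
    abort(sprintf(
      "duplicate record_id within a corpus: %s",
      paste(utils::head(dup, 5), collapse = ", ")
    ))
  }
  if (anyNA(x$title) || any(!nzchar(x$title))) {
    abort("every record needs a non-empty `title`")
  }
  for (i in seq_len(nrow(x))) {
    m <- x$mesh[[i]]
    if (!is.data.frame(m) || !all(c("descriptor", "subheadings", "major") %in% names(m))) {
      abort(sprintf("record %s: `mesh` must be a tibble with descriptor/subheadings/major", x$record_id[[i]]))
    }
    for (d in m$descriptor) validate_descriptor(d)
  }
  x
}

# Character vector of descriptors per record (list).
corpus_descriptors <- function(corpus) {
  lapply(corpus$mesh, function(m) m$descriptor)
}
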