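#' Read bibliographic records from a MEDLINE/PubMed flat file
#'
#' Parses the tagged MEDLINE export format (`PMID- `, `TI  - `, `AB  - `,
#' `MH  - `, `PT  - `, `DP  - `, ...). Records are separated by blank
#' lines; continuation lines (beginning with whitespace) are joined to the
#' previous field with a single space. Both the canonical two-space
#' separator (`MH  - `) and the one-space variant (`MH - `) are accepted,
#' since exports vary.
#'
#' `MH` values are normalised on read: a leading `*` becomes the
#' major-topic flag and `/`-separated subheadings are split off the
#' descriptor, so `*Heart Failure/drug therapy` is stored as descriptor
#' `"Heart Failure"`, subheading `"drug therapy"`, `major = TRUE`.
#' Substance-registry fields (`RN`, `NM`) are recognised but never treated
#' as subject headings. Text is normalised to composed (NFC) Unicode; case
#' is preserved in storage (all downstream matching is case-insensitive).
#'
#' Provenance tags written by [write_medline()] use the non-standard
#' `SRC` tag and are read back into `source_tags`.
#'
#' @param file Path to a MEDLINE flat file.
#' @param text Alternatively, a character vector of lines.
#' @return A corpus tibble (see [as_corpus()]); zero rows for empty input.
#'   Records lacking a `PMID` are dropped with a warning.
#' @export
read_medline <- function(file = NULL, text = NULL) {
  lines <- io_lines(file, text)
  blocks <- split_blocks(lines)
  recs <- purrr::compact(purrr::map(blocks, parse_medline_block))
  bind_records(recs)
}

io_lines <- function(file, text) {
  if (is.null(text)) {
    if (is.null(file)) abort("supply `file` or `text`")
    text <- readLines(file, encoding = "UTF-8", warn = FALSE)
  }
  stringi::stri_trans_nfc(enc2utf8(text))
}

# Split lines into per-record blocks on blank lines, keeping absolute
# line numbers for error messages.
split_blocks <- function(lines) {
  blank <- !nzchar(trimws(lines))
  grp <- cumsum(c(TRUE, diff(blank) == -1L))
  grp[blank] <- NA
  idx <- split(seq_along(lines)[!blank], grp[!blank])
  lapply(idx, function(i) list(lines = lines[i], lineno = i))
}

# Fold a tagged block into a tibble of (tag, value), joining continuation
# lines. `sep_rx` matches the tag prefix.
fold_tagged <- function(block, sep_rx, format) {
  tags <- character()
  vals <- character()
  for (j in seq_along(block$lines)) {
    ln <- block$lines[[j]]
    m <- regmatches(ln, regexec(sep_rx, ln))[[1]]
    if (length(m)) {
      tags <- c(tags, m[[2]])
      vals <- c(vals, m[[3]])
    } else if (grepl("^\\s", ln) && length(vals)) {
      vals[length(vals)] <- paste(vals[length(vals)], trimws(ln))
    } else {
      abort(sprintf("%s parse error at line %d: %s", format, block$lineno[[j]], ln))
    }
  }
  tibble(tag = tags, value = vals)
}

medline_sep_rx <- "^([A-Z][A-Z0-9]{0,3}) {0,2}- (.*)$"

parse_medline_block <- function(block) {
  fv <- fold_tagged(block, medline_sep_rx, "MEDLINE")
  pick <- function(tag) fv$value[fv$tag == tag]
  pmid <- pick("PMID")
  if (!length(pmid) || !nzchar(trimws(pmid[[1]]))) {
    warn(sprintf("record starting at line %d has no PMID; skipped", block$lineno[[1]]))
    return(NULL)
  }
  mh <- pick("MH")
  mesh <- if (length(mh)) {
    dplyr::bind_rows(lapply(mh, parse_mh_value))
  } else {
    empty_mesh()
  }
  dp <- pick("DP")
  year <- if (length(dp)) {
    y <- stringr::str_extract(dp[[1]], "\\d{4}")
    if (is.na(y)) NA_integer_ else as.integer(y)
  } else {
    NA_integer_
  }
  title <- pick("TI")
  if (!length(title)) {
    warn(sprintf("record PMID %s has no TI field; skipped", trimws(pmid[[1]])))
    return(NULL)
  }
  list(
    record_id = trimws(pmid[[1]]),
    title = title[[1]],
    abstract = if (length(pick("AB"))) pick("AB")[[1]] else "",
    mesh = mesh,
    pub_types = pick("PT"),
    source_tags = pick("SRC"),
    year = year
  )
}

# "*Heart Failure/drug therapy/mortality" -> parsed heading.
parse_mh_value <- function(value) {
  value <- trimws(value)
  major <- startsWith(value, "*")
  if (major) value <- sub("^\\*", "", value)
  parts <- strsplit(value, "/", fixed = TRUE)[[1]]
  # the major flag may also be attached to a subheading (e.g. "Heart
  # Failure/*drug therapy"); strip it there too
  if (any(startsWith(parts, "*"))) major <- TRUE
  parts <- sub("^\\*", "", parts)
  mesh_heading(parts[[1]], subheadings = parts[-1], major = major)
}

bind_records <- function(recs) {
  recs <- unname(recs)
  if (!length(recs)) {
    return(as_corpus(tibble(record_id = character(), title = character())))
  }
  as_corpus(tibble(
    record_id = purrr::map_chr(recs, "record_id"),
    title = purrr::map_chr(recs, "title"),
    abstract = purrr::map_chr(recs, "abstract"),
    mesh = purrr::map(recs, "mesh"),
    pub_types = purrr::map(recs, "pub_types"),
    source_tags = purrr::map(recs, "source_tags"),
    year = purrr::map_int(recs, "year")
  ))
}

#' Write a corpus as a MEDLINE flat file
#'
#' Inverse of [read_medline()]: the output re-parses to an equal corpus.
#' The major-topic flag is re-emitted as a leading asterisk and
#' subheadings are re-joined with `/`.
#'
#' @param corpus A corpus tibble.
#' @param file Path to write to, or `NULL` to only return the lines.
#' @return Invisibly, the character vector of lines.
#' @export
write_medline <- function(corpus, file = NULL) {
  corpus <- as_corpus(corpus)
  blocks <- purrr::pmap(corpus, function(record_id, title, abstract, mesh,
                                         pub_types, source_tags, year) {
    mh_lines <- purrr::pmap_chr(mesh, function(descriptor, subheadings, major) {
      paste0("MH  - ", if (major) "*" else "", paste(c(descriptor, subheadings), collapse = "/"))
    })
    c(
      paste0("PMID- ", record_id),
      if (!is.na(year)) paste0("DP  - ", year),
      paste0("TI  - ", title),
      if (nzchar(abstract)) paste0("AB  - ", abstract),
      mh_lines,
      if (length(pub_types)) paste0("PT  - ", pub_types),
      if (length(source_tags)) paste0("SRC - ", source_tags)
    )
  })
  lines <- unlist(purrr::map(blocks, function(b) c(b, "")), use.names = FALSE)
  lines <- utils::head(lines, -1L) # no trailing blank line
  if (length(lines) == 0L) lines <- character()
  if (!is.null(file)) writeLines(lines, file, useBytes = FALSE)
  invisible(lines)
}

ris_sep_rx <- "^([A-Z][A-Z0-9])  - (.*)$"

#' Read bibliographic records from an RIS file
#'
#' Maps RIS tags onto the corpus schema: `ID` (or `AN`) to `record_id`,
#' `TI`/`T1` to `title`, `AB`/`N2` to `abstract`, `KW` keywords verbatim to
#' MeSH descriptors (no subheading structure is assumed), `PY` to `year`,
#' `M3` to `pub_types` and `U1` to `source_tags`. Unknown tags are ignored
#' (reported when `options(hedgeR.verbose = TRUE)`).
#'
#' @inheritParams read_medline
#' @return A corpus tibble.
#' @export
read_ris <- function(file = NULL, text = NULL) {
  lines <- io_lines(file, text)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(bind_records(list()))
  ends <- grep("^ER  -", lines)
  if (!length(ends)) abort("RIS input has no ER record terminator")
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  recs <- purrr::map2(starts, ends, function(s, e) {
    parse_ris_block(list(lines = lines[s:e], lineno = s:e))
  })
  bind_records(purrr::compact(recs))
}

ris_known_tags <- c("TY", "ER", "ID", "AN", "TI", "T1", "AB", "N2", "KW", "PY", "M3", "U1")

parse_ris_block <- function(block) {
  fv <- fold_tagged(block, ris_sep_rx, "RIS")
  unknown <- setdiff(unique(fv$tag), ris_known_tags)
  if (length(unknown) && isTRUE(getOption("hedgeR.verbose"))) {
    rlang::inform(sprintf("RIS: ignoring tags %s", paste(unknown, collapse = ", ")))
  }
  pick <- function(tags) fv$value[fv$tag %in% tags]
  id <- pick(c("ID", "AN"))
  if (!length(id)) {
    warn(sprintf("RIS record at line %d has no ID/AN; skipped", block$lineno[[1]]))
    return(NULL)
  }
  title <- pick(c("TI", "T1"))
  if (!length(title)) {
    warn(sprintf("RIS record %s has no title; skipped", id[[1]]))
    return(NULL)
  }
  kw <- pick("KW")
  py <- pick("PY")
  year <- if (length(py)) {
    y <- stringr::str_extract(py[[1]], "\\d{4}")
    if (is.na(y)) NA_integer_ else as.integer(y)
  } else {
    NA_integer_
  }
  list(
    record_id = trimws(id[[1]]),
    title = title[[1]],
    abstract = if (length(pick(c("AB", "N2")))) pick(c("AB", "N2"))[[1]] else "",
    mesh = if (length(kw)) dplyr::bind_rows(lapply(kw, mesh_heading)) else empty_mesh(),
    pub_types = pick("M3"),
    source_tags = pick("U1"),
    year = year
  )
}

#' Write a corpus as an RIS file
#'
#' Inverse of [read_ris()] under its tag mapping. Subheadings and
#' major-topic flags have no RIS representation and are not emitted;
#' round-tripping through RIS keeps descriptors only.
#'
#' @inheritParams write_medline
#' @return Invisibly, the character vector of lines.
#' @export
write_ris <- function(corpus, file = NULL) {
  corpus <- as_corpus(corpus)
  blocks <- purrr::pmap(corpus, function(record_id, title, abstract, mesh,
                                         pub_types, source_tags, year) {
    c(
      "TY  - JOUR",
      paste0("ID  - ", record_id),
      paste0("TI  - ", title),
      if (nzchar(abstract)) paste0("AB  - ", abstract),
      if (nrow(mesh)) paste0("KW  - ", mesh$descriptor),
      if (!is.na(year)) paste0("PY  - ", year),
      if (length(pub_types)) paste0("M3  - ", pub_types),
      if (length(source_tags)) paste0("U1  - ", source_tags),
      "ER  - "
    )
  })
  lines <- unlist(purrr::map(blocks, function(b) c(b, "")), use.names = FALSE)
  lines <- utils::head(lines, -1L)
  if (length(lines) == 0L) lines <- character()
  if (!is.null(file)) writeLines(lines, file, useBytes = FALSE)
  invisible(lines)
}
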