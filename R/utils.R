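#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Round half-up (as printed tables do), not banker's rounding.
# The tiny offset guards against binary representations of x*10^d
# landing a hair under .5 (e.g. 100 * 23/88).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

# Percentage of a count over a set size, half-up to one decimal.
pct1 <- function(count, total) {
  round_half_up(100 * count / total, 1)
}

# Lowercase word tokens: runs of letters/digits, internal hyphens kept
# as part of a token ("double-blind" is one token). Everything else is
# a separator, so matching is punctuation-insensitive.
tokenize <- function(x) {
  stringr::str_extract_all(tolower(x), "[a-z0-9]+(?:-[a-z0-9]+)*")
}

# Space-padded token string per element, for contiguous token-sequence
# matching via fixed-string search: " chronic heart failure ".
pad_tokens <- function(x) {
  toks <- tokenize(x)
  vapply(toks, function(t) paste0(" ", paste(t, collapse = " "), " "), character(1))
}

# Canonical key for a term or descriptor: its padded token string.
term_key <- function(text) pad_tokens(text)

# Case/space-insensitive descriptor normalisation for .sh. equality.
norm_descriptor <- function(x) stringr::str_squish(tolower(x))

assert_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != floor(x)) {
    abort(sprintf("`%s` must be a single non-negative integer", name))
  }
  as.integer(x)
}
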