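# In-code corpus builders for unit and property tests.

# The published-table fixtures are deterministic but not free to build;
# cache one copy per test run.
fixtures_cached <- local({
  fx <- NULL
  function() {
    if (is.null(fx)) fx <<- table_fixtures()
    fx
  }
})
term_id_fixture_cached <- function() fixtures_cached()$term_id

toy_record <- function(id, title, abstract = "", mesh_descs = character(),
                       subheadings = list(), major = logical(), ...) {
  m <- if (length(mesh_descs)) {
    dplyr::bind_rows(lapply(seq_along(mesh_descs), function(i) {
      mesh_heading(
        mesh_descs[[i]],
        subheadings = if (length(subheadings) >= i) subheadings[[i]] else character(),
        major = if (length(major) >= i) major[[i]] else FALSE
      )
    }))
  } else {
    NULL
  }
  bib_record(id, title, abstract = abstract, mesh = m, ...)
}

toy_corpus <- function(...) merge_corpora(list(...))

word_pool <- c(
  "alpha", "beta", "gamma", "delta", "heart", "failure", "kidney",
  "lung", "renal", "acute", "chronic", "study", "cohort", "edema"
)
mesh_pool <- c(
  "Heart Failure", "Kidney Diseases", "Lung Diseases",
  "Cardiomyopathy, Dilated", "Pulmonary Edema", "Ventricular Dysfunction, Left"
)

random_corpus <- function(n, seed) {
  withr::with_seed(seed, {
    recs <- lapply(seq_len(n), function(i) {
      title <- paste(sample(word_pool, sample(3:7, 1), replace = TRUE), collapse = " ")
      abstract <- if (runif(1) < 0.8) {
        paste(sample(word_pool, sample(0:12, 1), replace = TRUE), collapse = " ")
      } else {
        ""
      }
      descs <- sample(mesh_pool, sample(0:3, 1))
      toy_record(sprintf("RC%04d", i), paste("record", i, title), abstract, descs)
    })
    merge_corpora(recs)
  })
}

random_terms <- function(k, seed) {
  withr::with_seed(seed, {
    texts <- replicate(k, paste(sample(word_pool, sample(1:2, 1)), collapse = " "))
    scopes <- sample(c("mp", "mp", "sh"), k, replace = TRUE)
    texts[scopes == "sh"] <- sample(mesh_pool, sum(scopes == "sh"), replace = TRUE)
    unik <- !duplicated(paste(tolower(texts), scopes))
    tibble::tibble(term = texts[unik], scope = scopes[unik])
  })
}
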