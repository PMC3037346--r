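test_that("mesh frequency counts distinct records, not heading repeats", {
  r1 <- bib_record("1", "T1", mesh = dplyr::bind_rows(
    mesh_heading("Heart Failure", "therapy"),
    mesh_heading("Heart Failure", "mortality", major = TRUE)
  ))
  r2 <- toy_record("2", "T2", mesh_descs = c("Heart Failure", "Humans"))
  r3 <- toy_record("3", "T3", mesh_descs = "Kidney Diseases")
  out <- mesh_frequency(toy_corpus(r1, r2, r3), exclusions = "humans")
  expect_equal(out$term, c("Heart Failure", "Kidney Diseases"))
  expect_equal(out$record_occurrence, c(2L, 1L))
  expect_equal(out$occurrence_pct, c(66.7, 33.3))
  expect_equal(out$scope, c("sh", "sh"))

  no_mesh <- toy_corpus(bib_record("9", "Plain"))
  expect_equal(nrow(mesh_frequency(no_mesh)), 0L)
  expect_error(mesh_frequency(no_mesh[0, ]), "empty")
})

test_that("mesh frequency ranks by occurrence then alphabetically", {
  corp <- merge_corpora(lapply(1:6, function(i) {
    toy_record(as.character(i), "T",
               mesh_descs = c(if (i <= 3) "Zeta Disease", if (i <= 3) "Alpha Disease",
                              if (i <= 5) "Mid Disease"))
  }))
  out <- mesh_frequency(corp, exclusions = character())
  expect_equal(out$term, c("Mid Disease", "Alpha Disease", "Zeta Disease"))
})

test_that("textword counts match a brute-force token tally", {
  corp <- toy_corpus(
    toy_record("1", "Heart failure and heart rate", "the failure of care"),
    toy_record("2", "Kidney outcomes", "heart heart heart"),
    toy_record("3", "Plain title", ""),
    toy_record("4", "Renal registry", "failure", mesh_descs = "Heart Failure"),
    toy_record("5", "The of and", "")
  )
  out <- textword_frequency(corp, stopwords = c("the", "of", "and"))
  # brute-force totals over title+abstract text
  all_tokens <- unlist(lapply(seq_len(nrow(corp)), function(i) {
    oracle_tokens(paste(corp$title[[i]], corp$abstract[[i]]))
  }))
  all_tokens <- all_tokens[!all_tokens %in% c("the", "of", "and")]
  for (w in unique(out$term)) {
    expect_equal(out$total_frequency[out$term == w], sum(all_tokens == w))
  }
  # record occurrence follows .mp. semantics (record 4's MeSH words count)
  expect_equal(out$record_occurrence[out$term == "heart"], 3L)
  expect_equal(out$record_occurrence[out$term == "failure"], 2L)
  # concordance ranking: by total frequency, descending
  expect_equal(out$term[[1]], "heart")
  # a corpus whose only text is stopwords yields nothing
  expect_equal(nrow(textword_frequency(corp[5, ], stopwords = c("the", "of", "and"))), 0L)
})

test_that("record occurrence equals single-term retrieval cardinality", {
  for (seed in c(3, 17)) {
    corp <- random_corpus(30, seed)
    tw <- textword_frequency(corp, stopwords = "the")
    for (i in seq_len(nrow(tw))) {
      expect_equal(
        tw$record_occurrence[[i]],
        length(retrieve(corp, search_strategy(tw$term[[i]], tw$scope[[i]])))
      )
    }
    ph <- phrase_candidates(corp, top_k_words = 5, min_records = 2)
    for (i in seq_len(nrow(ph))) {
      expect_equal(
        ph$record_occurrence[[i]],
        length(retrieve(corp, search_strategy(ph$term[[i]], ph$scope[[i]])))
      )
    }
  }
})

test_that("phrase discovery proposes trimmed n-grams with scan-verified counts", {
  corp <- toy_corpus(
    toy_record("1", "Left ventricular ejection fraction measured", "the ejection fraction improved"),
    toy_record("2", "Reduced left ventricular ejection fraction", ""),
    toy_record("3", "Singleword", "")
  )
  out <- phrase_candidates(corp, top_k_words = 10, max_len = 4)
  expect_true("left ventricular ejection fraction" %in% out$term)
  expect_equal(out$record_occurrence[out$term == "left ventricular ejection fraction"], 2L)
  expect_equal(out$record_occurrence[out$term == "ejection fraction"], 2L)
  # no phrase starts or ends with a stopword
  first_last <- unlist(lapply(strsplit(out$term, " "), function(t) t[c(1, length(t))]))
  expect_false(any(first_last %in% default_stopwords()))
  # single-word titles alone yield nothing
  expect_equal(nrow(phrase_candidates(corp[3, ], top_k_words = 3)), 0L)
})

test_that("curated phrase lists are scored and ranked as given terms", {
  corp <- toy_corpus(
    toy_record("1", "Heart failure cohort", "chronic heart failure"),
    toy_record("2", "Chronic kidney disease", "")
  )
  out <- phrase_candidates(corp, curated = c("chronic heart failure", "heart failure"))
  expect_equal(out$term, c("chronic heart failure", "heart failure"))
  expect_equal(out$record_occurrence, c(1L, 1L))
})

test_that("the cutoff keeps candidates at or above the derived threshold", {
  cut <- cutoff_spec(0.15, 88)
  expect_equal(cut$min_count, 13L)
  cand <- tibble::tibble(
    term = letters[1:6], scope = "mp",
    record_occurrence = c(20L, 13L, 12L, 5L, 88L, 0L),
    occurrence_pct = 0, set_size = 88L
  )
  kept <- apply_cutoff(cand, cut)
  expect_equal(kept$term, cand$term[cand$record_occurrence >= 13])  # filter oracle
  expect_equal(nrow(apply_cutoff(cand[cand$record_occurrence < 13, ], cut)), 0L)
})

test_that("stored percentages recompute from counts under half-up rounding", {
  fx <- term_id_fixture_cached()
  for (cand in list(
    mesh_frequency(fx),
    textword_frequency(fx),
    phrase_candidates(fx, curated = hf_phrase_list())
  )) {
    expect_equal(
      cand$occurrence_pct,
      floor(1000 * cand$record_occurrence / cand$set_size + 0.5 + 1e-9) / 10
    )
  }
})
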