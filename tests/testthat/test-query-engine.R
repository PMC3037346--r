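test_that("mp matching covers title, abstract and subject-heading words", {
  rec_title <- toy_record("1", "Chronic heart failure management")
  expect_true(match_records(rec_title, "heart failure", "mp"))
  # word boundaries: a term is not a substring match
  expect_false(match_records(rec_title, "art failure", "mp"))
  expect_false(match_records(rec_title, "failure management plan", "mp"))

  rec_mesh <- toy_record("2", "Outcome registry", "No key words here",
                         mesh_descs = "Cardiomyopathy, Dilated")
  expect_true(match_records(rec_mesh, "cardiomyopathy", "mp"))
  # punctuation-insensitive token sequences
  rec_punct <- toy_record("3", "Ventricular dysfunction (left): imaging")
  expect_true(match_records(rec_punct, "ventricular dysfunction, left", "mp"))
})

test_that("sh matching is exact descriptor equality without explosion", {
  rec <- toy_record("1", "Title", mesh_descs = c("Heart Failure", "Heart Failure, Systolic"))
  expect_true(match_records(rec, "heart failure", "sh"))
  expect_true(match_records(rec, "HEART  failure", "sh"))
  # no explosion and no partial matches: narrower heading is a different term
  rec2 <- toy_record("2", "Title", mesh_descs = "Heart Failure, Systolic")
  expect_false(match_records(rec2, "heart failure", "sh"))
  # subheadings and major flag are ignored
  rec3 <- bib_record("3", "Title",
                     mesh = mesh_heading("Heart Failure", "drug therapy", major = TRUE))
  expect_true(match_records(rec3, "heart failure", "sh"))
})

test_that("a record indexed only with an off-filter heading is not retrieved", {
  rec <- toy_record("1", "Fluid overload after admission",
                    "No filter words appear in this text.",
                    mesh_descs = "Pulmonary Edema")
  expect_length(retrieve(rec, hf_filter()), 0L)
})

test_that("OR retrieval equals the union of per-term retrievals", {
  expect_length(retrieve(random_corpus(10, 1), search_strategy(character())), 0L)
  for (seed in 1:12) {
    corp <- random_corpus(25, seed)
    terms <- random_terms(4, seed + 100)
    strat <- search_strategy(terms$term, terms$scope)
    got <- retrieve(corp, strat)
    per_term <- lapply(seq_len(nrow(strat)), function(i) {
      retrieve(corp, strat[i, ])
    })
    expect_setequal(got, unique(unlist(per_term)))
    # against the independent matcher
    expect_setequal(got, oracle_retrieve(corp, strat))
    # monotonicity: adding a term never shrinks the set
    for (k in seq_len(nrow(strat) - 1)) {
      expect_true(all(retrieve(corp, strat[seq_len(k), ]) %in%
                        retrieve(corp, strat[seq_len(k + 1), ])))
    }
  }
})

test_that("match is insensitive to record field order", {
  rec <- toy_record("1", "Alpha beta", "gamma delta",
                    mesh_descs = c("Heart Failure", "Kidney Diseases"))
  shuffled <- rec
  shuffled$mesh[[1]] <- shuffled$mesh[[1]][2:1, ]
  for (term in list(c("heart failure", "sh"), c("alpha beta", "mp"), c("kidney", "mp"))) {
    expect_equal(
      match_records(rec, term[[1]], term[[2]]),
      match_records(shuffled, term[[1]], term[[2]])
    )
  }
})

test_that("Ovid rendering is numbered with a final OR line", {
  expect_equal(
    render_ovid(hf_filter()),
    paste(
      "1 heart failure.mp.",
      "2 ventricular dysfunction, left.sh.",
      "3 cardiomyopathy.mp.",
      "4 left ventricular ejection fraction.mp.",
      "5 Or/1-4",
      sep = "\n"
    )
  )
  # single-term strategies carry no combine line
  expect_equal(render_ovid(search_strategy("heart failure")), "1 heart failure.mp.")
  expect_error(render_ovid(search_strategy(character())), "empty")
})

test_that("Ovid strategies parse back to themselves", {
  expect_equal(parse_ovid("1 heart failure.mp."),
               search_strategy("heart failure", "mp"))
  # tab-separated table layout parses too
  tbl <- c("1\theart failure.mp.", "2\tventricular dysfunction, left.sh.",
           "3\tcardiomyopathy.mp.", "4\tleft ventricular ejection fraction.mp.",
           "5\tOr/1-4")
  expect_equal(parse_ovid(tbl)$text, hf_filter()$text)
  expect_equal(parse_ovid(tbl)$scope, hf_filter()$scope)
  expect_error(parse_ovid("1 heart failure.tw."), "heart failure.tw.")
  for (seed in 1:10) {
    terms <- random_terms(5, seed)
    strat <- search_strategy(tolower(terms$term), terms$scope)
    expect_equal(parse_ovid(render_ovid(strat)), strat)
  }
})
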