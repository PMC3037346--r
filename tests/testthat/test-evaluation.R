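test_that("recall evaluation counts, misses and percentages cohere", {
  corp <- merge_corpora(lapply(1:10, function(i) {
    bib_record(as.character(i), if (i <= 8) "heart failure cohort" else "renal cohort")
  }))
  strat <- search_strategy("heart failure")
  ev <- recall_eval(strat, corp)
  expect_equal(ev$retrieved, 8L)
  expect_equal(ev$set_size, 10L)
  expect_equal(ev$recall_pct, 80)
  expect_setequal(ev$missed_ids, c("9", "10"))
  expect_equal(ev$retrieved + length(ev$missed_ids), ev$set_size)
  # cross-module consistency
  expect_equal(ev$retrieved, length(retrieve(corp, strat)))
  # full-coverage case
  ev2 <- recall_eval(strat, corp[1:8, ])
  expect_equal(ev2$recall_pct, 100)
  expect_length(ev2$missed_ids, 0L)
  expect_error(recall_eval(strat, corp[0, ]), "empty")
  # adding a term never lowers recall
  wider <- dplyr::bind_rows(strat, search_strategy("renal", label = "T2"))
  expect_gte(recall_eval(wider, corp)$retrieved, ev$retrieved)
})

test_that("precision equals the labelled share of the first n retrievals", {
  corp <- merge_corpora(lapply(1:30, function(i) {
    bib_record(as.character(i), "heart failure series")
  }))
  strat <- search_strategy("heart failure")
  labels <- tibble::tibble(record_id = corp$record_id, relevant = TRUE)
  expect_equal(precision_screen(strat, corp, 20, labels)$precision_pct, 100)
  for (seed in 1:5) {
    lab <- withr::with_seed(seed, dplyr::mutate(labels, relevant = runif(30) < 0.6))
    ps <- precision_screen(strat, corp, 20, lab)
    # counting oracle over the first 20 in corpus order
    expect_equal(ps$relevant_n, sum(lab$relevant[1:20]))
    expect_equal(ps$precision_pct, round(100 * ps$relevant_n / 20, 1))
  }
  # yes/no labels and missing labels
  lab_chr <- dplyr::mutate(labels, relevant = "yes")
  expect_equal(precision_screen(strat, corp, 20, lab_chr)$relevant_n, 20L)
  expect_error(precision_screen(strat, corp, 20, labels[1:10, ]), "missing relevance labels")
  expect_error(precision_screen(strat, corp, 40, labels), "only 30")
})

test_that("missed-record MeSH reports tally descriptors over misses only", {
  fx <- fixtures_cached()
  ev <- recall_eval(hf_filter(), fx$validation)
  rep <- missed_report(ev, fx$validation)
  expect_equal(rep$descriptor, c("Pulmonary edema", "Implantable defibrillators",
                                 "Coronary disease", "Heart transplantation"))
  expect_equal(rep$n, c(3L, 2L, 1L, 1L))
  # brute-force tally oracle
  missed <- fx$validation[fx$validation$record_id %in% ev$missed_ids, ]
  brute <- sort(table(unlist(lapply(missed$mesh, function(m) m$descriptor))), decreasing = TRUE)
  expect_equal(sum(rep$n), sum(brute))
  # no misses, no rows
  ev_full <- recall_eval(hf_filter(), fx$validation[1:100, ])
  expect_equal(nrow(missed_report(ev_full, fx$validation[1:100, ])), 0L)
})

test_that("false-positive attribution matches a leave-one-term-out oracle", {
  fx <- fixtures_cached()
  attr <- false_positive_attribution(hf_filter(), fx$irrelevant)
  strat <- hf_filter()
  for (i in seq_len(nrow(strat))) {
    expect_equal(
      attr$matched[[i]],
      length(retrieve(fx$irrelevant, strat[i, ]))
    )
    expect_equal(
      attr$unique_contribution[[i]],
      length(retrieve(fx$irrelevant, strat)) -
        length(retrieve(fx$irrelevant, strat[-i, ]))
    )
  }
  # single-term strategy: everything it retrieves is its own unique share
  sub <- fx$irrelevant[match_records(fx$irrelevant, "heart failure", "mp"), ]
  solo <- false_positive_attribution(search_strategy("heart failure"), sub)
  expect_equal(solo$matched, nrow(sub))
  expect_equal(solo$unique_contribution, nrow(sub))
  # records outside the strategy's reach are refused
  expect_error(
    false_positive_attribution(search_strategy("nomatchword"), fx$irrelevant),
    "not retrieved"
  )
})

test_that("recall and precision are invariant to duplicating every record", {
  corp <- random_corpus(20, 31)
  strat <- search_strategy(c("heart failure", "kidney"), c("mp", "mp"))
  doubled <- merge_corpora(list(
    corp,
    dplyr::mutate(corp, record_id = paste0("copy-", record_id))
  ))
  expect_equal(recall_eval(strat, doubled)$recall_pct, recall_eval(strat, corp)$recall_pct)
  labels <- tibble::tibble(
    record_id = doubled$record_id,
    relevant = rep(c(TRUE, FALSE), length.out = nrow(doubled))
  )
  n_ret <- length(retrieve(doubled, strat))
  if (n_ret >= 4) {
    ps <- precision_screen(strat, doubled, 4, labels)
    expect_equal(ps$precision_pct, 100 * ps$relevant_n / 4)
  }
})

test_that("specificity is correct exclusions over the irrelevant total", {
  irrelevant <- merge_corpora(lapply(1:8, function(i) {
    bib_record(as.character(i), if (i <= 2) "heart failure mention" else "renal cohort")
  }))
  sp <- specificity_eval(search_strategy("heart failure"), irrelevant)
  expect_equal(sp$excluded, 6L)
  expect_equal(sp$specificity_pct, 75)
})
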