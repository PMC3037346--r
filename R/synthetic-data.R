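# Fixed noise vocabulary for generated text: neutral clinical-report
# words, deliberately free of cardiology topic terms. Words colliding
# with declared planted terms are filtered out again at generation time.
noise_vocabulary <- c(
  "analysis", "assessment", "baseline", "clinical", "cohort", "comparison",
  "consecutive", "controlled", "criteria", "design", "duration", "effect",
  "eligibility", "endpoint", "enrolment", "evaluation", "evidence",
  "examination", "findings", "groups", "hospital", "imaging", "incidence",
  "inclusion", "intervention", "investigation", "management", "measurement",
  "methods", "monitoring", "observation", "outcomes", "participants",
  "patients", "population", "procedure", "prognosis", "protocol",
  "quality", "randomisation", "recruitment", "registry", "report",
  "response", "results", "sample", "screening", "setting", "significance",
  "subjects", "surveillance", "therapy", "treatment", "variables", "visits"
)

#' Specify a synthetic corpus
#'
#' Declares the statistical structure of a generated corpus: per-term
#' occurrence probabilities by field, and nesting rules that make a
#' dependent term occur *only* in records that also carry its anchor term
#' (with a given conditional probability). Nesting emulates the synonym
#' structure that drives zero-marginal-gain elimination during filter
#' development: a perfectly nested synonym never adds records to its
#' anchor.
#'
#' @param n_records Number of records.
#' @param terms A data frame with columns `term`, `field` (one of
#'   `"title"`, `"abstract"`, `"mesh"`) and `prob` (marginal occurrence
#'   probability in `[0, 1]`).
#' @param nested Optional data frame with columns `term`, `field`,
#'   `anchor`, `prob`: `term` occurs with probability `prob` in records
#'   containing `anchor` (a term declared in `terms`) and never elsewhere.
#' @param abstract_words Mean number of noise words per abstract
#'   (Poisson).
#' @param abstract_empty_prob Probability a record has no abstract.
#' @param n_noise_words Size of the noise vocabulary actually used.
#' @param seed Integer seed; generation is reproducible from it.
#' @return A `corpus_spec` list.
#' @export
corpus_spec <- function(n_records, terms = NULL, nested = NULL,
                        abstract_words = 25, abstract_empty_prob = 0,
                        n_noise_words = 40, seed = 1L) {
  n_records <- assert_scalar_count(n_records, "n_records")
  terms <- if (is.null(terms)) {
    tibble(term = character(), field = character(), prob = numeric())
  } else {
    as_tibble(terms)
  }
  nested <- if (is.null(nested)) {
    tibble(term = character(), field = character(), anchor = character(), prob = numeric())
  } else {
    as_tibble(nested)
  }
  stopifnot(all(c("term", "field", "prob") %in% names(terms)))
  if (nrow(nested)) stopifnot(all(c("term", "field", "anchor", "prob") %in% names(nested)))
  if (!all(terms$field %in% c("title", "abstract", "mesh")) ||
      !all(nested$field %in% c("title", "abstract", "mesh"))) {
    abort('`field` must be "title", "abstract" or "mesh"')
  }
  if (any(terms$prob < 0 | terms$prob > 1) || any(nested$prob < 0 | nested$prob > 1)) {
    abort("occurrence probabilities must be in [0, 1]")
  }
  if (nrow(nested) && !all(nested$anchor %in% terms$term)) {
    abort("every nested `anchor` must be declared in `terms`")
  }
  if (abstract_empty_prob < 0 || abstract_empty_prob > 1) {
    abort("`abstract_empty_prob` must be in [0, 1]")
  }
  structure(
    list(
      n_records = n_records, terms = terms, nested = nested,
      abstract_words = abstract_words,
      abstract_empty_prob = abstract_empty_prob,
      n_noise_words = n_noise_words, seed = as.integer(seed)
    ),
    class = "corpus_spec"
  )
}

#' Generate a synthetic corpus
#'
#' Draws a corpus from a [corpus_spec()]: every record gets a noise-word
#' title and abstract (the abstract possibly empty), planted terms appear
#' in their declared fields with their declared probabilities, and nested
#' terms appear only where their anchor does. Same seed, same corpus.
#'
#' @param spec A [corpus_spec()].
#' @param id_prefix Prefix for record ids.
#' @return A corpus tibble.
#' @export
generate_corpus <- function(spec, id_prefix = "S") {
  if (!inherits(spec, "corpus_spec")) abort("`spec` must be a corpus_spec()")
  n <- spec$n_records
  if (n == 0L) return(bind_records(list()))
  planted_tokens <- unique(unlist(tokenize(c(spec$terms$term, spec$nested$term)),
                                  use.names = FALSE))
  vocab <- setdiff(noise_vocabulary, planted_tokens)
  vocab <- utils::head(vocab, max(spec$n_noise_words, 5L))
  withr::with_seed(spec$seed, {
    occur <- matrix(FALSE, n, nrow(spec$terms),
                    dimnames = list(NULL, spec$terms$term))
    for (j in seq_len(nrow(spec$terms))) {
      occur[, j] <- stats::runif(n) < spec$terms$prob[[j]]
    }
    nest_occur <- matrix(FALSE, n, nrow(spec$nested),
                         dimnames = list(NULL, spec$nested$term))
    for (j in seq_len(nrow(spec$nested))) {
      anchor_on <- occur[, spec$nested$anchor[[j]]]
      nest_occur[, j] <- anchor_on & (stats::runif(n) < spec$nested$prob[[j]])
    }
    recs <- vector("list", n)
    for (i in seq_len(n)) {
      title_terms <- c(
        spec$terms$term[occur[i, ] & spec$terms$field == "title"],
        spec$nested$term[nest_occur[i, ] & spec$nested$field == "title"]
      )
      abstract_terms <- c(
        spec$terms$term[occur[i, ] & spec$terms$field == "abstract"],
        spec$nested$term[nest_occur[i, ] & spec$nested$field == "abstract"]
      )
      mesh_terms <- c(
        spec$terms$term[occur[i, ] & spec$terms$field == "mesh"],
        spec$nested$term[nest_occur[i, ] & spec$nested$field == "mesh"]
      )
      title <- paste(
        c(sample(vocab, 3L), title_terms, sample(vocab, 1L)),
        collapse = " "
      )
      abstract <- if (stats::runif(1) < spec$abstract_empty_prob) {
        ""
      } else {
        n_words <- stats::rpois(1, spec$abstract_words)
        paste(
          c(sample(vocab, min(n_words, length(vocab))), abstract_terms),
          collapse = " "
        )
      }
      recs[[i]] <- list(
        record_id = sprintf("%s%05d", id_prefix, i),
        title = title, abstract = abstract,
        mesh = if (length(mesh_terms)) {
          dplyr::bind_rows(lapply(mesh_terms, mesh_heading))
        } else {
          empty_mesh()
        },
        pub_types = character(), source_tags = character(),
        year = NA_integer_
      )
    }
    bind_records(recs)
  })
}

table2_counts <- function() {
  hf <- search_strategy("heart failure", "mp")
  vdl <- search_strategy("ventricular dysfunction, left", "sh")
  cm <- search_strategy("cardiomyopathy", "mp")
  lvef <- search_strategy("left ventricular ejection fraction", "mp")
  comb <- function(...) dplyr::bind_rows(...)
  tibble(
    strategy = list(
      hf,
      comb(hf, lvef),
      comb(hf, cm),
      comb(hf, vdl),
      comb(hf, cm, lvef),
      comb(hf, cm, vdl),
      comb(hf, vdl, lvef),
      comb(hf, vdl, cm),
      comb(hf, vdl, cm, lvef)
    ),
    retrieved = c(365L, 372L, 373L, 373L, 378L, 380L, 376L, 380L, 382L)
  )
}

#' The nine shortlisted heart failure candidate terms
#'
#' The candidate set that survives the 15% record-occurrence cutoff in
#' the worked heart failure example: two subject headings and seven
#' textwords/phrases.
#'
#' @return A tibble with columns `term` and `scope`.
#' @export
hf_candidates <- function() {
  tibble(
    term = c(
      "heart failure", "ventricular dysfunction, left",
      hf_phrase_list()
    ),
    scope = c("sh", "sh", rep("mp", length(hf_phrase_list())))
  )
}

#' Deterministic fixtures reproducing the published development tables
#'
#' Emits self-verified corpora whose retrieval counts reproduce the
#' printed tables of the worked heart failure filter study:
#'
#' * `term_id` — 88 records matching every published term-identification
#'   record occurrence (e.g. MeSH *Heart failure* in 62 records, textword
#'   *heart failure* in 77), with check-tag MeSH for the exclusion list
#'   and below-cutoff decoy terms.
#' * `development` — 394 records reconstructed from the development
#'   table's per-strategy counts (single best term 365; final four-term
#'   filter 382), with the four perfectly nested synonym textwords and
#'   the *Heart Failure* subject heading planted inside the dominant
#'   term so they show zero marginal gain.
#' * `validation` — 394 records, 7 planted misses carrying the reported
#'   off-filter MeSH (*Pulmonary edema* n=3, *Coronary disease* n=1,
#'   *Heart transplantation* n=1, *Implantable defibrillators* n=2).
#' * `cochrane` — 269 records, 6 planted misses.
#' * `screening` — a list with a 210-record corpus and relevance
#'   `labels`: of the first 200 retrieved records 150 are relevant, the
#'   50 irrelevant ones carrying the reported term attribution.
#' * `irrelevant` — the 50 irrelevant screened records as a corpus.
#'
#' Every fixture is verified against its published counts on emission;
#' an infeasible table would error here (and does not, for the shipped
#' tables).
#'
#' @return A named list of fixtures.
#' @export
table_fixtures <- function() {
  out <- list(
    term_id = term_id_fixture(),
    development = development_fixture(),
    validation = validation_fixture(),
    cochrane = cochrane_fixture()
  )
  scr <- screening_fixture()
  out$screening <- scr
  out$irrelevant <- scr$corpus[!scr$labels$relevant, , drop = FALSE]
  verify_fixtures(out)
  out
}

term_id_fixture <- function() {
  n <- 88L
  recs <- lapply(seq_len(n), function(i) {
    title <- if (i <= 77) {
      sprintf("Term identification record %03d: heart failure management", i)
    } else {
      sprintf("Term identification record %03d: vascular outcomes registry", i)
    }
    ab <- c(
      "Background synthetic abstract text.",
      if (i <= 36) "Patients with congestive heart failure were enrolled.",
      if (i <= 24) "Symptoms were graded by new york heart association class.",
      if (i <= 23) "Mean left ventricular ejection fraction was measured.",
      if (i <= 20) "Outcomes in chf cohorts were recorded.",
      if (i <= 17) "Participants had chronic heart failure at baseline.",
      if (i <= 15) "Echocardiography suggested cardiomyopathy in several cases.",
      if (i <= 9) "Plasma natriuretic peptide concentrations were obtained.",
      if (i <= 5) "Assessment noted diastolic dysfunction on imaging."
    )
    mh <- c(
      if (i <= 62) "Heart Failure",
      if (i <= 14) "Ventricular Dysfunction, Left",
      if (i <= 12) "Stroke Volume",
      if (i <= 9) "Prognosis",
      "Humans",
      if (i <= 60) "Male",
      if (i <= 55) "Female",
      if (i <= 45) "Aged",
      if (i <= 40) "Middle Aged"
    )
    list(
      record_id = sprintf("TI%03d", i), title = title,
      abstract = paste(ab, collapse = " "),
      mesh = dplyr::bind_rows(lapply(mh, mesh_heading)),
      pub_types = "Journal Article", source_tags = character(),
      year = 2005L + (i %% 4L)
    )
  })
  bind_records(recs)
}

development_fixture <- function() {
  fx <- reconstruct_fixture(table2_counts(), n_records = 394L, id_prefix = "D")
  corpus <- fx$corpus
  # The dominant-term atom is built first, so records 1..365 are the
  # heart failure.mp matches. Nest the eliminated synonyms (and the
  # Heart Failure subject heading) inside it: they retrieve on their own
  # but add nothing over T1.
  stopifnot(grepl("heart failure", corpus$title[1:365]))
  add_ab <- function(idx, txt) {
    corpus$abstract[idx] <<- trimws(paste(corpus$abstract[idx], txt))
  }
  add_ab(1:40, "Enrolled patients had congestive heart failure.")
  add_ab(1:20, "Registry chf outcomes were recorded.")
  add_ab(41:57, "Participants had chronic heart failure at baseline.")
  add_ab(10:33, "Severity followed new york heart association class.")
  corpus$mesh[1:300] <- lapply(corpus$mesh[1:300], function(m) {
    dplyr::bind_rows(m, mesh_heading("Heart Failure"))
  })
  validate_corpus(corpus)
}

planted_miss_corpus <- function(n, n_hit, misses, id_prefix) {
  # n_hit retrieved records; misses = named counts of MeSH descriptors
  # for the non-retrieved remainder
  stopifnot(n_hit + sum(misses) == n)
  recs <- vector("list", n)
  for (i in seq_len(n_hit)) {
    # vary which filter term retrieves the record
    kind <- i %% 20L
    if (kind == 0L) {
      title <- sprintf("Gold record %03d: dilated cardiomyopathy outcomes", i)
      mesh <- empty_mesh()
    } else if (kind == 1L) {
      title <- sprintf("Gold record %03d: systolic dysfunction cohort", i)
      mesh <- mesh_heading("Ventricular Dysfunction, Left")
    } else if (kind == 2L) {
      title <- sprintf("Gold record %03d: reduced left ventricular ejection fraction", i)
      mesh <- empty_mesh()
    } else {
      title <- sprintf("Gold record %03d: heart failure cohort study", i)
      mesh <- if (i %% 2L) mesh_heading("Heart Failure", "therapy") else empty_mesh()
    }
    recs[[i]] <- list(
      record_id = sprintf("%s%03d", id_prefix, i), title = title,
      abstract = "Synthetic gold standard abstract.", mesh = mesh,
      pub_types = character(), source_tags = character(), year = NA_integer_
    )
  }
  i <- n_hit
  for (d in names(misses)) {
    for (r in seq_len(misses[[d]])) {
      i <- i + 1L
      recs[[i]] <- list(
        record_id = sprintf("%s%03d", id_prefix, i),
        title = sprintf("Gold record %03d: acute decompensation admission", i),
        abstract = "Synthetic gold standard abstract.",
        mesh = mesh_heading(d),
        pub_types = character(), source_tags = character(), year = NA_integer_
      )
    }
  }
  bind_records(recs)
}

validation_fixture <- function() {
  planted_miss_corpus(
    394L, 387L,
    c(
      "Pulmonary edema" = 3L, "Coronary disease" = 1L,
      "Heart transplantation" = 1L, "Implantable defibrillators" = 2L
    ),
    id_prefix = "V"
  )
}

cochrane_fixture <- function() {
  planted_miss_corpus(
    269L, 263L,
    c(
      "Pulmonary edema" = 1L, "Edema" = 2L, "Chronic diseases" = 1L,
      "Cardiovascular diseases" = 1L, "Heart diseases" = 1L
    ),
    id_prefix = "C"
  )
}

screening_fixture <- function() {
  n <- 210L
  # among the first 200 retrieved: every 4th record is irrelevant (50);
  # the irrelevant ones carry the reported per-term attribution
  irrelevant_pos <- seq(4L, 200L, by = 4L)
  irr_kind <- rep(
    c("hf_text", "hf_mesh", "cardiomyopathy", "vdl", "lvef"),
    times = c(17L, 9L, 11L, 11L, 2L)
  )
  recs <- vector("list", n)
  ki <- 0L
  labels <- logical(n)
  for (i in seq_len(n)) {
    if (i %in% irrelevant_pos) {
      ki <- ki + 1L
      kind <- irr_kind[[ki]]
      labels[[i]] <- FALSE
      rec <- switch(kind,
        hf_text = list(
          title = sprintf("Screened record %03d: heart failure mentioned in passing", i),
          mesh = empty_mesh()
        ),
        hf_mesh = list(
          title = sprintf("Screened record %03d: perioperative monitoring", i),
          mesh = mesh_heading("Heart Failure", "etiology")
        ),
        cardiomyopathy = list(
          title = sprintf("Screened record %03d: screening relatives", i),
          mesh = mesh_heading("Cardiomyopathy, Dilated")
        ),
        vdl = list(
          title = sprintf("Screened record %03d: postinfarction imaging", i),
          mesh = mesh_heading("Ventricular Dysfunction, Left", "ultrasonography")
        ),
        lvef = list(
          title = sprintf("Screened record %03d: left ventricular ejection fraction methodology", i),
          mesh = empty_mesh()
        )
      )
    } else {
      labels[[i]] <- TRUE
      rec <- list(
        title = sprintf("Screened record %03d: heart failure management", i),
        mesh = mesh_heading("Heart Failure")
      )
    }
    recs[[i]] <- list(
      record_id = sprintf("P%03d", i), title = rec$title,
      abstract = "Synthetic screened abstract.", mesh = rec$mesh,
      pub_types = character(), source_tags = character(), year = NA_integer_
    )
  }
  corpus <- bind_records(recs)
  list(
    corpus = corpus,
    labels = tibble(record_id = corpus$record_id, relevant = labels)
  )
}

verify_fixtures <- function(fx) {
  check <- function(ok, what) {
    if (!isTRUE(ok)) abort(sprintf("fixture self-verification failed: %s", what))
  }
  idx <- corpus_index(fx$term_id)
  occ <- function(text, scope) sum(match_with_index(idx, text, scope))
  t1 <- c(
    occ("heart failure", "sh") == 62, occ("ventricular dysfunction, left", "sh") == 14,
    occ("heart failure", "mp") == 77, occ("congestive heart failure", "mp") == 36,
    occ("new york heart association", "mp") == 24,
    occ("left ventricular ejection fraction", "mp") == 23,
    occ("chf", "mp") == 20, occ("chronic heart failure", "mp") == 17,
    occ("cardiomyopathy", "mp") == 15
  )
  check(all(t1), "term identification record occurrences")
  t2 <- table2_counts()
  for (i in seq_len(nrow(t2))) {
    check(
      length(retrieve(fx$development, t2$strategy[[i]])) == t2$retrieved[[i]],
      sprintf("development strategy %d", i)
    )
  }
  check(length(retrieve(fx$validation, hf_filter())) == 387, "validation retrieval")
  check(length(retrieve(fx$cochrane, hf_filter())) == 263, "cochrane retrieval")
  first200 <- utils::head(retrieve(fx$screening$corpus, hf_filter()), 200)
  rel <- fx$screening$labels$relevant[match(first200, fx$screening$labels$record_id)]
  check(length(first200) == 200 && sum(rel) == 150, "screening labels")
  invisible(fx)
}
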