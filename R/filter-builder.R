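#' Develop a filter by greedy recall-maximising forward selection
#'
#' Implements the objective filter development procedure. Every candidate
#' is first searched singly in the development set; the term with the
#' highest retrieval (T1) is selected. Each later step trials every
#' remaining candidate OR-combined with the current baseline and selects
#' the one adding the most records. A candidate showing zero marginal
#' gain at any evaluation is eliminated immediately and never
#' reconsidered (under OR monotonicity a later baseline could not
#' resurrect it). Selection stops when no remaining candidate adds a
#' record; the strategy retrieving the maximal number of records is the
#' filter.
#'
#' Ties on retrieval count are resolved by `tie_break`; with
#' `explore_ties = TRUE` (default) each tied runner-up also spawns an
#' alternative branch whose subsequent evaluations are recorded in the
#' trace (tied candidates are labelled `T2(a)`, `T2(b)`, ...), so
#' converging tie branches are documented the way published development
#' tables report them. Alternative branches resolve their own further
#' ties by policy without spawning again.
#'
#' @param candidates A tibble with columns `term` and `scope` (as produced
#'   by the term-identification functions), at least one row.
#' @param development A non-empty corpus tibble (the filter development set).
#' @param tie_break `"alphabetical"` (case-insensitive term text, then
#'   scope) or `"input"` (candidate order as given).
#' @param explore_ties Record alternative tie branches in the trace?
#' @return A `filter_trace` object: a list with
#'   * `trace` — tibble of every evaluation: `branch`, `step`,
#'     `baseline`, `label`, `term`, `scope`, `retrieved`, `gain`,
#'     `recall_pct`, `action` (`selected` / `evaluated` / `eliminated`);
#'   * `strategy` — the selected strategy tibble;
#'   * `eliminated` — tibble of dropped candidates with step and reason;
#'   * `set_size`, `final_retrieved`, `final_recall_pct`, `tie_break`.
#' @seealso [autoplot.filter_trace()], [generics::tidy()],
#'   [generics::glance()]
#' @export
greedy_build <- function(candidates, development,
                         tie_break = c("alphabetical", "input"),
                         explore_ties = TRUE) {
  tie_break <- match.arg(tie_break)
  if (!nrow(candidates)) abort("`candidates` must contain at least one term")
  development <- as_corpus(development)
  n <- nrow(development)
  if (!n) abort("`development` corpus is empty")
  cand <- tibble(term = candidates$term, scope = candidates$scope)
  if (anyDuplicated(paste(tolower(cand$term), cand$scope))) {
    abort("candidate terms must be unique (term + scope)")
  }
  idx <- corpus_index(development)
  M <- vapply(seq_len(nrow(cand)), function(i) {
    match_with_index(idx, cand$term[[i]], cand$scope[[i]])
  }, logical(n))
  M <- matrix(M, nrow = n) # n records x k candidates

  policy_order <- function(i) {
    if (tie_break == "alphabetical") i[order(tolower(cand$term[i]), cand$scope[i])] else sort(i)
  }

  run_branch <- function(branch, hit, selected, labels, remaining, step,
                         forced = NULL, spawn = FALSE) {
    rows <- list()
    elim <- list()
    spawned <- list()
    repeat {
      if (!length(remaining)) break
      base_n <- sum(hit)
      baseline <- paste(labels, collapse = " OR ")
      cnt <- vapply(remaining, function(i) sum(hit | M[, i]), integer(1))
      gain <- cnt - base_n
      zero <- gain == 0L
      best <- max(cnt)
      tied <- policy_order(remaining[cnt == best & !zero])
      pick <- if (!is.null(forced)) forced else if (length(tied)) tied[[1]] else NA_integer_
      forced <- NULL
      tie_lab <- NULL
      if (length(tied) > 1L) {
        tie_lab <- stats::setNames(
          sprintf("T%d(%s)", step, letters[seq_along(tied)]), tied
        )
      }
      lab_of <- function(i) {
        if (!is.null(tie_lab) && as.character(i) %in% names(tie_lab)) {
          tie_lab[[as.character(i)]]
        } else {
          sprintf("T%d", step)
        }
      }
      ord <- policy_order(remaining)
      for (i in ord) {
        j <- match(i, remaining)
        action <- if (zero[[j]]) "eliminated" else if (identical(i, pick)) "selected" else "evaluated"
        rows[[length(rows) + 1L]] <- tibble(
          branch = branch, step = step, baseline = baseline,
          label = if (action == "eliminated") NA_character_ else lab_of(i),
          term = cand$term[[i]], scope = cand$scope[[i]],
          retrieved = cnt[[j]], gain = gain[[j]],
          recall_pct = pct1(cnt[[j]], n), action = action
        )
        if (zero[[j]]) {
          elim[[length(elim) + 1L]] <- tibble(
            term = cand$term[[i]], scope = cand$scope[[i]], step = step,
            reason = if (base_n == 0L) "retrieves no records" else {
              sprintf("no additional records over %s", baseline)
            }
          )
        }
      }
      remaining <- remaining[!zero]
      if (is.na(pick) || !length(remaining)) break
      if (spawn && length(tied) > 1L) {
        for (alt in tied[-1L]) {
          spawned[[length(spawned) + 1L]] <- list(
            branch = gsub("[^a-z]", "", sub("^T\\d+", "", tie_lab[[as.character(alt)]])),
            hit = hit, selected = selected, labels = labels,
            remaining = remaining, step = step, forced = alt
          )
        }
      }
      hit <- hit | M[, pick]
      selected <- c(selected, pick)
      labels <- c(labels, lab_of(pick))
      remaining <- setdiff(remaining, pick)
      step <- step + 1L
    }
    list(rows = rows, selected = selected, labels = labels, elim = elim,
         final = sum(hit), spawned = spawned)
  }

  main <- run_branch("main", rep(FALSE, n), integer(), character(),
                     seq_len(nrow(cand)), 1L, spawn = explore_ties)
  rows <- main$rows
  elim <- main$elim
  for (sp in main$spawned) {
    altname <- sprintf("alt-%s@T%d", sp$branch, sp$step)
    alt <- run_branch(altname, sp$hit, sp$selected, sp$labels,
                      sp$remaining, sp$step, forced = sp$forced)
    rows <- c(rows, alt$rows)
  }
  trace <- dplyr::bind_rows(rows)
  # keep only the main branch's eliminations in the summary table
  eliminated <- if (length(elim)) dplyr::bind_rows(elim) else {
    tibble(term = character(), scope = character(), step = integer(), reason = character())
  }
  strategy <- search_strategy(
    cand$term[main$selected], cand$scope[main$selected], label = main$labels
  )
  structure(
    list(
      trace = trace,
      strategy = strategy,
      eliminated = eliminated,
      set_size = n,
      final_retrieved = main$final,
      final_recall_pct = pct1(main$final, n),
      tie_break = tie_break
    ),
    class = "filter_trace"
  )
}

#' @export
print.filter_trace <- function(x, ...) {
  cat(sprintf(
    "<filter_trace> %d-term filter; %d/%d records (recall %.1f%%)\n",
    nrow(x$strategy), x$final_retrieved, x$set_size, x$final_recall_pct
  ))
  cat("Selected strategy:\n")
  cat(paste0("  ", render_ovid_lines(x$strategy)), sep = "\n")
  if (nrow(x$eliminated)) {
    cat(sprintf(
      "Eliminated: %s\n",
      paste(x$eliminated$term, collapse = "; ")
    ))
  }
  invisible(x)
}

render_ovid_lines <- function(strategy) {
  strsplit(render_ovid(strategy), "\n", fixed = TRUE)[[1]]
}

#' Reconstruct a development corpus from published retrieval counts
#'
#' Builds a synthetic corpus of a stated size whose planted term
#' memberships make every listed OR strategy retrieve exactly its listed
#' count — so a printed development table fully determines a working
#' fixture. The listed union cardinalities are solved by
#' inclusion-exclusion for the sizes of all membership atoms over the
#' strategies' terms; atoms the table does not determine are left empty
#' (satellite terms get no members beyond those the printed unions
#' force), a deterministic completion that also preserves the printed
#' single-term ranking. Inconsistent or under-determined tables are
#' rejected with the violated constraint named. The emitted corpus is
#' re-verified against every listed count before it is returned.
#'
#' The solvable family is the one development tables print: every row's
#' term set must contain the common core (typically the baseline term),
#' the full union of all terms must be listed, and every subset of the
#' non-core terms must appear as some row's complement.
#'
#' @param rows A tibble with a list-column `strategy` (each element a
#'   strategy tibble) and an integer column `retrieved`.
#' @param n_records Total corpus size (at least the full union's count).
#' @param id_prefix Prefix for generated record ids.
#' @return A list with `corpus` (the reconstructed corpus tibble),
#'   `terms` (strategy tibble of all distinct terms) and `atoms` (tibble
#'   of term-membership atoms and their record counts).
#' @export
reconstruct_fixture <- function(rows, n_records, id_prefix = "R") {
  n_records <- assert_scalar_count(n_records, "n_records")
  if (!nrow(rows)) abort("`rows` must list at least one strategy")
  terms <- dplyr::distinct(
    dplyr::bind_rows(rows$strategy)[, c("text", "scope")]
  )
  k <- nrow(terms)
  term_id <- function(strategy) {
    sort(match(
      paste(tolower(strategy$text), strategy$scope),
      paste(tolower(terms$text), terms$scope)
    ))
  }
  sets <- lapply(rows$strategy, term_id)
  keys <- vapply(sets, paste, character(1), collapse = ",")
  u <- as.integer(rows$retrieved)
  if (anyNA(u) || any(u < 0)) abort("`retrieved` counts must be non-negative integers")
  for (kk in unique(keys[duplicated(keys)])) {
    if (length(unique(u[keys == kk])) > 1L) {
      abort(sprintf("conflicting counts for the same strategy {%s}", kk))
    }
  }
  keep <- !duplicated(keys)
  sets <- sets[keep]; u <- u[keep]; keys <- keys[keep]
  core <- Reduce(intersect, sets)
  free <- setdiff(seq_len(k), core)
  subset_key <- function(s) {
    if (!length(s)) "{}" else paste(sort(s), collapse = ",")
  }
  u_of <- stats::setNames(u, vapply(sets, subset_key, character(1)))
  full_key <- subset_key(seq_len(k))
  if (!full_key %in% names(u_of)) {
    abort("the full union of all terms must be listed (it anchors the total)")
  }
  n_in <- u_of[[full_key]]
  if (n_in > n_records) {
    abort(sprintf("full union (%d) exceeds n_records (%d)", n_in, n_records))
  }
  # v(T) = records whose memberships lie inside core+T = n_in - u(K \ T)
  free_subsets <- free_powerset(free)
  v <- numeric(length(free_subsets))
  for (i in seq_along(free_subsets)) {
    comp <- c(core, setdiff(free, free_subsets[[i]]))
    if (!length(comp)) {
      v[[i]] <- n_in # u(empty strategy) = 0
      next
    }
    comp_key <- subset_key(comp)
    if (!comp_key %in% names(u_of)) {
      abort(sprintf(
        "under-determined table: no row fixes the union of terms {%s}",
        paste(terms$text[comp], collapse = ", ")
      ))
    }
    v[[i]] <- n_in - u_of[[comp_key]]
  }
  names(v) <- vapply(free_subsets, subset_key, character(1))
  # Moebius inversion for atom sizes over the free terms
  atoms <- list()
  for (i in seq_along(free_subsets)) {
    a <- free_subsets[[i]]
    if (!length(a)) next
    x <- 0
    for (T in free_powerset(a)) {
      x <- x + (-1)^(length(a) - length(T)) * v[[subset_key(T)]]
    }
    if (x < -1e-9) {
      abort(sprintf(
        "infeasible cardinality system: membership atom {%s} would need %d records",
        paste(terms$text[a], collapse = " & "), as.integer(round(x))
      ))
    }
    if (x > 0) atoms[[length(atoms) + 1L]] <- list(members = a, count = as.integer(round(x)))
  }
  core_mass <- n_in - v[[subset_key(free)]] # = u(core)
  if (core_mass < 0) abort("infeasible cardinality system: core mass negative")
  if (length(core) && core_mass > 0) {
    atoms <- c(list(list(members = core, count = as.integer(core_mass))), atoms)
  } else if (!length(core) && core_mass > 0) {
    abort("infeasible cardinality system: unassignable core mass without a common core term")
  }
  corpus <- build_atom_corpus(atoms, terms, n_records, id_prefix)
  # self-check: every listed strategy must retrieve exactly its count
  for (i in seq_along(sets)) {
    st <- terms[sets[[i]], , drop = FALSE]
    got <- length(retrieve(corpus, search_strategy(st$text, st$scope)))
    if (got != u[[i]]) {
      abort(sprintf(
        "reconstruction self-check failed for strategy {%s}: expected %d, retrieved %d",
        paste(terms$text[sets[[i]]], collapse = " OR "), u[[i]], got
      ))
    }
  }
  atom_tbl <- dplyr::bind_rows(lapply(atoms, function(a) {
    tibble(terms = paste(terms$text[a$members], collapse = " & "), count = a$count)
  }))
  list(
    corpus = corpus,
    terms = search_strategy(terms$text, terms$scope),
    atoms = atom_tbl
  )
}

free_powerset <- function(s) {
  out <- list(integer())
  for (e in s) out <- c(out, lapply(out, function(t) c(t, e)))
  out
}

# Materialise atom records: mp terms go into the title, sh terms become
# MeSH descriptors. Background records use vocabulary chosen not to
# collide with filter terms (verified by the caller's self-check).
build_atom_corpus <- function(atoms, terms, n_records, id_prefix) {
  recs <- list()
  i <- 0L
  for (a in atoms) {
    mp <- terms$text[a$members][terms$scope[a$members] == "mp"]
    sh <- terms$text[a$members][terms$scope[a$members] == "sh"]
    for (r in seq_len(a$count)) {
      i <- i + 1L
      title <- if (length(mp)) {
        sprintf("Synthetic record %04d: %s", i, paste(mp, collapse = " and "))
      } else {
        sprintf("Synthetic record %04d: subject-heading indexed", i)
      }
      mesh <- if (length(sh)) {
        dplyr::bind_rows(lapply(sh, mesh_heading))
      } else {
        empty_mesh()
      }
      recs[[i]] <- list(
        record_id = sprintf("%s%04d", id_prefix, i),
        title = title, abstract = "", mesh = mesh,
        pub_types = character(), source_tags = character(), year = NA_integer_
      )
    }
  }
  n_bg <- n_records - i
  for (r in seq_len(n_bg)) {
    i <- i + 1L
    recs[[i]] <- list(
      record_id = sprintf("%s%04d", id_prefix, i),
      title = sprintf("Synthetic nonmatching background citation %04d", i),
      abstract = "", mesh = empty_mesh(),
      pub_types = character(), source_tags = character(), year = NA_integer_
    )
  }
  bind_records(recs)
}
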