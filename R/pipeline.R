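#' Run the whole filter development pipeline
#'
#' Orchestrates the six study phases end to end: read and merge tagged
#' record sets, deduplicate, apply the abstract filter, split into term
#' identification / development / validation sets, run frequency
#' analysis and the cutoff, develop the filter greedily on the
#' development set, and validate recall on the held-out set. All
#' artifacts are written to `out_dir` as plain-text tables, plus the
#' filter in Ovid syntax and a run log recording the seed and every
#' decision parameter. Reruns with the same configuration produce
#' byte-identical artifacts.
#'
#' @param config A named list (or path to a YAML file with the same
#'   fields):
#'   \describe{
#'     \item{inputs}{character vector of record files}
#'     \item{format}{`"medline"` (default) or `"ris"`}
#'     \item{fractions}{three split proportions (default 0.10/0.45/0.45)}
#'     \item{seed}{integer (default 1)}
#'     \item{cutoff_fraction}{record-occurrence cutoff (default 0.15)}
#'     \item{tie_break}{`"alphabetical"` (default) or `"input"`}
#'     \item{stopwords, exclusions, phrases}{optional paths to one-term-per-line
#'       overrides for the bundled lists}
#'     \item{exclude_ids}{optional path to record ids judged irrelevant,
#'       removed before splitting (relevance judgments are inputs here)}
#'     \item{out_dir}{output directory (created)}
#'   }
#' @return Invisibly, a list with the split, the candidate tables, the
#'   `filter_trace` and the validation `retrieval_eval`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(
    list(
      format = "medline", fractions = c(0.10, 0.45, 0.45), seed = 1L,
      cutoff_fraction = 0.15, tie_break = "alphabetical",
      stopwords = NULL, exclusions = NULL, phrases = NULL,
      exclude_ids = NULL, out_dir = "hedge-run"
    ),
    config
  )
  if (is.null(cfg$inputs)) abort("config needs `inputs`: at least one record file")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  read_list <- function(path, default) {
    if (is.null(path)) default else readLines(path, encoding = "UTF-8")
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(cfg$out_dir, "run_log.txt")
  log_lines <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    rlang::inform(msg)
  }
  say("hedgeR %s pipeline run", as.character(utils::packageVersion("hedgeR")))
  say("seed: %d; fractions: %s; cutoff fraction: %g; tie break: %s",
      cfg$seed, paste(cfg$fractions, collapse = "/"), cfg$cutoff_fraction,
      cfg$tie_break)

  reader <- if (cfg$format == "ris") read_ris else read_medline
  corpora <- stage("read", lapply(cfg$inputs, reader))
  gold <- stage("merge_dedup", merge_corpora(corpora))
  say("merged %d input file(s): %d unique records", length(cfg$inputs), nrow(gold))
  if (!is.null(cfg$exclude_ids)) {
    drop <- readLines(cfg$exclude_ids, encoding = "UTF-8")
    gold <- gold[!gold$record_id %in% drop, , drop = FALSE]
    say("excluded %d records judged irrelevant", length(drop))
  }
  ab <- stage("abstract_filter", require_abstract(gold))
  say("abstract filter: kept %d, excluded %d", nrow(ab$kept), nrow(ab$excluded))
  sp <- stage("split", split_corpus(ab$kept, split_spec(cfg$fractions, cfg$seed)))
  say("split sizes: term_id %d / development %d / validation %d",
      nrow(sp$term_id), nrow(sp$development), nrow(sp$validation))
  write_tsv(sp$manifest, file.path(cfg$out_dir, "split_manifest.tsv"))

  stopw <- read_list(cfg$stopwords, default_stopwords())
  excl <- read_list(cfg$exclusions, default_mesh_exclusions())
  mesh_cand <- stage("mesh_frequency", mesh_frequency(sp$term_id, excl))
  tw_cand <- stage("textword_frequency", textword_frequency(sp$term_id, stopw))
  phr_cand <- stage("phrase_candidates", phrase_candidates(
    sp$term_id, stopwords = stopw,
    curated = if (is.null(cfg$phrases)) NULL else readLines(cfg$phrases, encoding = "UTF-8")
  ))
  write_tsv(mesh_cand, file.path(cfg$out_dir, "mesh_candidates.tsv"))
  write_tsv(tw_cand[, setdiff(names(tw_cand), "total_frequency")],
            file.path(cfg$out_dir, "textword_candidates.tsv"))
  write_tsv(phr_cand, file.path(cfg$out_dir, "phrase_candidates.tsv"))

  cut <- cutoff_spec(cfg$cutoff_fraction, nrow(sp$term_id))
  say("cutoff: >= %d of %d records", cut$min_count, cut$set_size)
  shortlist <- dplyr::bind_rows(
    apply_cutoff(mesh_cand, cut),
    apply_cutoff(if (is.null(cfg$phrases)) {
      dplyr::bind_rows(
        tw_cand[, names(phr_cand)],
        phr_cand
      )
    } else {
      phr_cand
    }, cut)
  )
  # a phrase list may restate single words already shortlisted
  shortlist <- shortlist[!duplicated(paste(tolower(shortlist$term), shortlist$scope)), ]
  write_tsv(shortlist, file.path(cfg$out_dir, "shortlist.tsv"))
  say("shortlisted candidates: %d", nrow(shortlist))
  if (!nrow(shortlist)) abort("pipeline stage 'cutoff' failed: no candidate survives")

  trace <- stage("greedy_build", greedy_build(
    shortlist, sp$development, tie_break = cfg$tie_break
  ))
  write_tsv(trace$trace, file.path(cfg$out_dir, "trace.tsv"))
  writeLines(render_ovid(trace$strategy), file.path(cfg$out_dir, "filter.txt"))
  say("selected %d-term filter: %d/%d development records (recall %.1f%%)",
      nrow(trace$strategy), trace$final_retrieved, trace$set_size,
      trace$final_recall_pct)

  val <- stage("validation", recall_eval(trace$strategy, sp$validation))
  say("validation recall: %d/%d (%.1f%%)", val$retrieved, val$set_size,
      val$recall_pct)
  report <- dplyr::bind_rows(
    dplyr::mutate(glance(trace), set = "development", .before = 1),
    tibble(
      set = "validation", set_size = val$set_size,
      retrieved = val$retrieved, recall_pct = val$recall_pct
    )
  )
  write_tsv(report, file.path(cfg$out_dir, "evaluation.tsv"))
  writeLines(log_lines, logf)
  invisible(list(
    split = sp, mesh_candidates = mesh_cand, textword_candidates = tw_cand,
    phrase_candidates = phr_cand, shortlist = shortlist,
    trace = trace, validation = val, config = cfg
  ))
}

write_tsv <- function(x, path) {
  x <- as.data.frame(lapply(x, function(col) {
    if (is.list(col)) vapply(col, paste, character(1), collapse = ";") else col
  }))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}
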