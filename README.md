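# hedgeR

Objective development and validation of bibliographic search filters
(*hedges*) for MEDLINE-style databases.

Clinicians and systematic reviewers need pre-tested Boolean strategies
with known retrieval performance: a topic filter that reliably finds,
say, the heart failure literature without drowning the searcher in
irrelevant records. hedgeR implements the objective development
methodology end to end, for anyone building or auditing such a filter:

1. **Gold standard assembly** — read MEDLINE flat-file or RIS records,
   merge source-tagged sets, deduplicate with provenance-tag
   transferral, exclude records without abstracts.
2. **Random splitting** into Term Identification (10%), Filter
   Development (45%) and Filter Validation (45%) sets, seeded and
   manifest-logged.
3. **Term identification** — MeSH descriptor and title/abstract
   textword/phrase frequency analysis; *record occurrence* counts; a
   15% record-occurrence cutoff (`n >= round(0.15 N)`).
4. **Greedy filter development** — emulated OvidSP retrieval (`.mp.` =
   title/abstract/subject-heading words, `.sh.` = exact descriptor, OR
   combination, no truncation or explosion); forward selection of the
   candidate with the largest marginal retrieval, immediate elimination
   of zero-gain candidates, tie branches traced.
5. **Validation** — recall in held-out sets, missed-record MeSH
   reports, post-hoc precision screening of the first *n* retrievals,
   per-term false-positive attribution.

At each step the core quantity is simple set algebra over record sets:
recall is |retrieved ∩ gold| / |gold|, a greedy step selects
argmax_t |R(baseline ∪ {t})|, and a term is eliminated the first time
|R(baseline ∪ {t})| = |R(baseline)|. A synthetic corpus generator
(planted per-field term probabilities, nested synonyms) and a
reconstruction tool that turns a published development table's union
cardinalities into a working corpus make the whole pipeline testable
without any database access.

## Worked example

The package ships deterministic fixtures reproducing the published
development of the four-term heart failure filter. Reconstruct the
394-record Filter Development Set from its printed per-strategy counts
and develop the filter:

```r
library(hedgeR)

fx <- table_fixtures()          # self-verified worked-example corpora
trace <- greedy_build(hf_candidates(), fx$development)
trace
#> <filter_trace> 4-term filter; 382/394 records (recall 97.0%)
#> Selected strategy:
#>   1 heart failure.mp.
#>   2 cardiomyopathy.mp.
#>   3 ventricular dysfunction, left.sh.
#>   4 left ventricular ejection fraction.mp.
#>   5 Or/1-4
#> Eliminated: chf; chronic heart failure; congestive heart failure; heart failure; new york heart association
```

The best single term (`heart failure.mp.`) retrieves 365/394 records
(recall 92.6%); four synonym textwords retrieve on their own but add
nothing over it and are eliminated; the selected four-term filter
retrieves 382/394. `tidy(trace)` returns every evaluation, including
the explored tie branch between `cardiomyopathy.mp.` and `ventricular
dysfunction, left.sh.` (both 373), and `autoplot(trace)` draws the
development path.

Validate recall in the held-out sets and estimate precision from the
labelled screening fixture:

```r
glance(recall_eval(hf_filter(), fx$validation))
#> # A tibble: 1 × 4
#>   retrieved set_size recall_pct n_missed
#> 1       387      394       98.2        7

missed_report(recall_eval(hf_filter(), fx$validation), fx$validation)
#> # A tibble: 4 × 2
#>   descriptor                     n
#> 1 Pulmonary edema                3
#> 2 Implantable defibrillators     2
#> 3 Coronary disease               1
#> 4 Heart transplantation          1

glance(precision_screen(hf_filter(), fx$screening$corpus, 200, fx$screening$labels))
#> # A tibble: 1 × 3
#>   screened_n relevant_n precision_pct
#> 1        200        150            75
```

So in the held-out validation set the filter misses 7 of 394 records
(all indexed with headings outside the filter, such as *Pulmonary
edema*), and of the first 200 screened retrievals 150 are relevant — a
post-hoc precision estimate of 75%.

For your own data the entry points are `read_medline()` / `read_ris()`,
`merge_corpora()`, `require_abstract()`, `split_corpus()`,
`mesh_frequency()` / `textword_frequency()` / `phrase_candidates()`,
`apply_cutoff()`, `greedy_build()` and the evaluation functions — or
`run_pipeline()` (also wrapped by the thin CLI in `inst/cli/hedgeR.R`),
which runs all phases from a YAML config and writes plain-text
artifacts. The methods vignette
(`vignettes/filter-development.Rmd`) documents the model, parameters
and design choices.

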