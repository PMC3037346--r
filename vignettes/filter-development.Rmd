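---
title: "Objective development and validation of bibliographic search filters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Objective development and validation of bibliographic search filters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hedgeR)
library(dplyr)
```

## The problem

A search filter (a *hedge*) is a pre-tested Boolean search strategy with
known retrieval performance in a specific bibliographic database.
Clinicians and review teams searching MEDLINE for a clinical topic such
as heart failure face a trade-off: a single obvious term misses records
indexed or phrased differently, while broad ad hoc strategies drown the
user in irrelevant results. Filter development replaces guesswork with
measurement: starting from a *gold standard* of known-relevant records,
candidate terms are identified by frequency analysis, combined by OR in
the order of their measured marginal contribution, and the resulting
strategy's recall is validated in held-out record sets.

hedgeR implements that methodology end to end for MEDLINE-style records,
together with a synthetic corpus generator and a fixture reconstructor
so every stage is testable without database access. The worked example
throughout is the four-term heart failure filter

```
1 heart failure.mp.
2 ventricular dysfunction, left.sh.
3 cardiomyopathy.mp.
4 left ventricular ejection fraction.mp.
5 Or/1-4
```

whose development trace, validation recalls and post-hoc precision the
package's test suite reproduces from reconstructed fixtures.

## The procedure and its assumptions

**Gold standard assembly.** Records are read from MEDLINE flat files (or
RIS), tagged with their source (e.g. the clinical practice guideline
whose bibliography supplied them), merged, and deduplicated by record
id; a surviving record accumulates the union of its duplicates' tags, so
provenance is never lost. Records without abstracts are then excluded —
term identification needs abstract text, and relevance usually cannot be
judged from a title alone. Because the gold standard contains only
relevant records, recall is the only measure computable inside it;
precision requires labelled retrievals from outside (see below).
Relevance screening itself is out of scope: human judgments enter only
as inputs (an exclusion-id list, a label table).

**Splitting.** `split_corpus()` partitions the gold standard into a Term
Identification Set (10%), a Filter Development Set (45%) and a Filter
Validation Set (45%) by a seeded uniform random permutation with prefix
slicing. Sizes depend only on the corpus size and fractions (876 records
give 88/394/394; the 10% share is rounded half-up, and an odd remainder
goes to the development set — the halving convention had to be fixed
somewhere, and this one is recorded in the split manifest along with the
seed).

**Term identification.** `mesh_frequency()` counts, per distinct MeSH
descriptor, the number of distinct records indexed with it (*record
occurrence*); major-topic flags and subheadings are ignored, and a
shipped, editable exclusion list removes check tags and descriptors for
gender, age group, species and study design, which describe the study
rather than the topic. `textword_frequency()` tokenises titles and
abstracts (lowercase; split on anything that is not a letter, digit or
internal hyphen; no stemming, no truncation) and ranks words by total
frequency with stopwords removed. `phrase_candidates()` proposes
contiguous n-grams around the most frequent words; since a *meaningful*
phrase — one that stands as an independent concept, like "left
ventricular ejection fraction" as opposed to the bare adjective "left
ventricular" — is a human judgment, the function accepts a curated term
list that overrides discovery, and the worked heart failure list ships
as `hf_phrase_list()`. `apply_cutoff()` then keeps candidates retrieving
at least 15% of the set, as an integer threshold `round(0.15 * N)`
(13 of 88). The threshold is a study parameter, not a tuned value: a
lower cutoff admits rarer terms with possibly high discriminatory value
at the cost of a longer development phase.

Record occurrence for textwords and phrases is computed through the
query engine's `.mp.` matching, so a candidate's count always equals
what it would retrieve — one invariant the test suite checks across
modules. (Counting title/abstract text only would differ for terms that
appear solely as subject-heading words; on the shipped fixtures, where
MeSH assignments are nested inside text occurrences, both definitions
coincide.)

**Retrieval semantics.** The query engine emulates the two OvidSP field
suffixes the methodology uses. `.mp.` matches a term's token sequence
contiguously, case- and punctuation-insensitively, at word boundaries,
in the title, the abstract, or the word sequence of any MeSH descriptor
("cardiomyopathy" therefore retrieves a record indexed *Cardiomyopathy,
Dilated* even when the word never appears in its text). `.sh.` requires
case-insensitive equality with a descriptor; subheadings and major flags
are ignored, and there is no tree explosion — deliberately, since the
methodology searches headings unexploded, and structurally, since no
MeSH tree ships with the package. Subheading text is not searched by
`.mp.`: whether it should be is ambiguous, and descriptor-words-only is
the narrower, documented choice. Ovid's additional `.mp.` fields
(original title, substance names) are likewise out of scope because
parsed records need not carry them. Strategies combine terms by OR only;
AND, NOT, adjacency and limits are non-goals.

**Greedy development.** `greedy_build()` evaluates every candidate
singly, selects the top retriever (T1), then repeatedly adds the
candidate with the largest marginal contribution over the current
baseline, eliminating any candidate the first time it shows zero
marginal gain. Under OR monotonicity an eliminated candidate could never
contribute later, so early elimination is safe (the tests verify the
final retrieved set equals that of a never-eliminating oracle). The
procedure stops when no candidate adds records — a coverage criterion,
not a recall target. Ties are resolved alphabetically by default, and
tied candidates are labelled `T2(a)`, `T2(b)`, … with each runner-up's
branch explored and recorded in the trace, because published development
tables report both branches of a tie and both must be reproducible.
Greedy forward selection is per-step optimal, not globally optimal —
minimal set cover is a non-goal; what the method promises, and what the
per-step oracle tests check, is that each added term is the best single
addition at that moment.

**Evaluation.** `recall_eval()` reports retrieved/set-size and missed
ids; `missed_report()` tallies the MeSH indexing of missed records,
which is how one learns what lies beyond the filter's reach (records
indexed only with *Pulmonary edema*, for instance). Precision is
estimated post hoc with `precision_screen()`: the first *n* retrievals
(corpus order stands in for the database's default ordering, and is a
recorded parameter) are screened by a human whose labels are an input.
`false_positive_attribution()` decomposes an irrelevant retrieved set by
term, reporting per-term match counts and unique contributions, the
quantity that tells you whether removing a term would actually improve
precision. `specificity_eval()` exists for the completeness of the
definitions but requires an irrelevant-labelled corpus.

**Percentages.** All percentages are half-up to one decimal, applied
uniformly, with raw counts always retained. Published tables are not
always internally consistent at the last decimal (62/88 appears in
print as both 70.4% and 70.5%; 15/88 = 17.045% prints as 17.1%;
382/394 = 96.95% prints as 96.9%), so tests and acceptance comparisons
key on counts wherever possible and on the package's uniform rounding
otherwise.

## Synthetic data and fixtures

`generate_corpus()` draws corpora with controlled structure: per-term
occurrence probabilities by field (title, abstract, MeSH) over a fixed
noise vocabulary, plus nesting rules making a dependent term occur only
where its anchor does. Nesting is the statistical phenomenon behind
zero-marginal-gain elimination — a synonym that only ever accompanies
the dominant term adds nothing under OR — and the property suite checks
both the exhaustive never-without-anchor guarantee and that empirical
occurrence rates land within three binomial standard errors of their
specification at n = 2000.

What the generator emulates is occurrence structure only. It does not
model biomedical language, indexing policy drift, citation structure or
correlated noise vocabulary; passing tests on generated corpora show the
*algorithms* are correct under the declared occurrence model, not that
any particular filter will perform comparably on live MEDLINE.

`reconstruct_fixture()` builds a corpus from a printed development
table: given per-strategy union cardinalities, it solves by
inclusion–exclusion for the sizes of all term-membership atoms, rejects
infeasible or under-determined tables naming the violated constraint,
and self-verifies the emitted corpus against every listed count. Atoms
the table leaves undetermined are left empty — satellite terms get no
members beyond what the printed unions force. This completion is the one
consistent with the published trace: nesting satellites inside the
dominant term instead would inflate their single-term retrievals above
the dominant term's own, contradicting the printed step-one ranking.
The development table fully determines the overlap structure outside the
dominant term (for the heart failure table: 6 records reachable only
via *cardiomyopathy*, 4 only via *Ventricular dysfunction, Left*, 2 only
via *left ventricular ejection fraction*, 3 shared by the latter two, 1
by cardiomyopathy and ejection fraction, and 1 by all three satellites —
17 in all beyond T1's 365).

`table_fixtures()` assembles the full worked-example set: an 88-record
term identification corpus matching every published record occurrence, a
394-record development corpus reconstructed as above with the four
nested synonym textwords and the *Heart Failure* subject heading planted
inside the dominant term, validation (394, 7 planted misses) and
external-validation (269, 6 planted misses) corpora, and a 210-record
screening corpus with relevance labels in which 150 of the first 200
retrievals are relevant and the 50 irrelevant ones carry the reported
per-term attribution. Intersections beyond the printed counts are fixed
by the deterministic constructions above, so the fixtures are stable
across releases and every emission self-verifies. The external
validation set is sized 269 following the results as printed (263/269
retrieved), noting that its methods text says 263.

## Numerical and degenerate-input choices

* Rounding: half-up everywhere (`floor(x * 10 + 0.5) / 10` with a
  `1e-9` guard against binary representation of values like
  `100 * 23/88` landing a hair under `.5`).
* Tokens: `[a-z0-9]+(-[a-z0-9]+)*` after lowercasing — internal hyphens
  bind ("double-blind" is one token), all other punctuation separates.
* Empty inputs: frequency analysis and recall refuse empty corpora;
  parsers return zero-row corpora for empty streams; an empty strategy
  retrieves nothing; a single-term strategy renders without an `Or/1-1`
  line (Ovid has no such idiom).
* Records lacking a PMID or title are skipped with a warning; a
  malformed tag line is an error naming the line number.
* Ties: alphabetical by lowercase term text, then scope — a total,
  reproducible order; both members of a selection tie are traced.
* Seeds: every stochastic operation (splitting, generation) takes an
  explicit integer seed and records it in its output.

## Problem sizes

The shipped fixtures are desk-scale by construction (88–394 records;
the property suites use corpora of 20–100 records over 3–6 candidates,
and 100 generator seeds for planted-filter recovery), so the whole test
suite and the acceptance script run in well under a minute on one CPU.
These sizes were chosen to exercise every code path at the scale the
methodology itself operates — gold standards of around a thousand
records — not to stress-test throughput; matching is vectorised fixed-
string search over padded token strings and handles corpora orders of
magnitude larger without special handling.

## Known limitations

* `.mp.` here covers title, abstract and subject-heading descriptor
  words only; live OvidSP adds fields (substance names, original
  titles) that parsed exports may lack, so counts against a live system
  can differ slightly.
* No MeSH tree: explosion is unsupported by design, and the semantic
  exclusion list is a flat editable file, not a vocabulary service.
* Phrase discovery is a proposal heuristic; the methodology's
  "meaningful phrase" judgment is human and enters via the curated
  list.
* The dedup key is the record id; title-based fuzzy matching is out of
  scope since records drawn from a single database carry stable ids.
* Reconstruction supports the table family development traces print
  (every row containing the common baseline, full union present); it is
  not a general solver for arbitrary union systems.
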