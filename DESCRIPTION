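Package: hedgeR
Title: Objective Development and Validation of Bibliographic Search Filters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building topic-based Boolean search filters (hedges)
    for MEDLINE from a gold standard of known-relevant bibliographic records.
    Reads and writes MEDLINE flat-file and RIS records; assembles, deduplicates
    and randomly splits gold-standard corpora; identifies candidate terms by
    MeSH and textword frequency analysis with a record-occurrence cutoff;
    emulates OvidSP field-suffix retrieval (.mp./.sh.) with OR combination;
    develops filters by greedy recall-maximising forward selection with a full
    development trace; and validates recall and post-hoc precision in held-out
    sets. Includes a synthetic corpus generator and reconstruction of
    development corpora from published per-strategy retrieval counts, so the
    whole pipeline is testable without database access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
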