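Package: lexdb
Title: Lexical-Statistics Databases from Dependency-Parsed Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds disambiguated word-form and lemma frequency databases from
    CoNLL-U (Universal Dependencies) corpora for psycholinguistic stimulus
    selection. Entries are keyed by lemma, word class, surface form and a core
    morphological feature string. Derived statistics include raw and per-million
    relative frequencies, average bigram and initial/final trigram frequencies,
    two ambiguity measures (form ambiguity and lemma ambiguity), and a filtered
    orthographic neighborhood size (Hamming distance 1). Databases are queried
    with a small AND-conjunctive query language, or via word and lemma lists;
    letter n-gram statistics can be computed for nonword stimuli. A thin
    command-line interface covers database building, merging, pruning, querying
    and export.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
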