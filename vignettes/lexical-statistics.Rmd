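---
title: "Lexical statistics from dependency-parsed corpora: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lexical statistics from dependency-parsed corpora: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lexdb)
library(data.table)
```

## The problem

Stimulus selection for word-recognition experiments needs per-word norms:
how frequent a surface form and its lemma are, how long it is, how common its
letter n-grams are, how many orthographic neighbors it has, and — in
morphologically rich languages — how *ambiguous* it is, i.e. how likely the
same letter string is to be a form of some other lemma or word class.
`lexdb` derives all of these from dependency-parsed corpora in CoNLL-U
format, where every token already carries a lemma, a Universal Dependencies
word class (UPOS) and a morphological feature set.

The central modeling assumption is that the parse is *noisy but
frequency-faithful*: individual analyses may be wrong (web-crawled corpora
tagged by neural parsers contain systematically mis-tagged tokens), but
incorrect analyses are predominantly rare. Every design choice below — the
token pre-filter, frequency pruning, the 1 % ambiguity allowance and the
frequency-gated neighborhood — follows from that assumption.

## The database

A database is an exact aggregation: one row per distinct quadruple
*(lemma, word class, surface form, core feature string)* with its token
count. Using the feature string in the key is what makes the data
*disambiguated*: Finnish *silmäsi* ('your eye(s)') is stored as three rows
under the noun *silmä* — plural nominative, singular genitive, singular
nominative — rather than one conflated count.

Only eleven UD features enter the key: case, number, person, possessor
person and number, clitic, derivation, verb form, mood, tense, voice. This
is a balance: these features are the ones users actually query, while
features such as `Degree`, `Polarity` or style markers would multiply rows
without adding searchable value. Dropping them at projection time means two
tokens differing only in a dropped feature merge into one row.

**Canonical serialization.** Two feature sets are equal iff their
serializations are equal, so serialization must be canonical. We serialize
`Key=Value` pairs joined by `|` in the fixed order Case, Number, Person,
Person[psor], Number[psor], Clitic, Derivation, VerbForm, Mood, Tense,
Voice, and the empty set as `_` (the CoNLL-U convention). A fixed list —
rather than e.g. the incidental order of the input — guarantees key equality
across files and merges. Note this order is positional, not alphabetical, so
a serialized string can differ cosmetically from a UD source line while
denoting the same feature set.

**Token filter.** A token is counted only if *both* its form and its lemma
(after lowercasing, which happens first) pass: all characters in the
language charset (for Finnish: `a–z å ä ö š ž`, digits, internal hyphen and
apostrophe), first character alphanumeric, at least one letter, length 2–100.
Filtering both fields jointly is the conservative reading — a wordlike form
with a garbage lemma is parser noise. The 100-character ceiling is
deliberately loose: real Finnish words max out between 30 and 40 characters,
and longer strings are overwhelmingly artifacts of HTML boilerplate, but a
loose ceiling costs nothing once frequency pruning is applied.

**Compounds.** Finnish UD lemmas mark compound boundaries with `#`
(`linja#auto`). The separator is the only compound signal available in
parsed data, so a row is flagged `compound` iff its lemma contains the
separator; the separator is then stripped so stored lemmas stay plain
orthographic strings that queries can match.

**Merging and pruning.** Large corpora are built per input file and merged:
shared keys sum their frequencies, totals sum. Single-pass and sharded
builds are identical by construction, and the test suite asserts this
additivity on random splits. Pruning removes rows below a minimum frequency
and rows in the classes `PUNCT`, `SYM`, `X`, then *recomputes* the token
total. All derived statistics are computed strictly after pruning, so
relative values always describe the data actually stored.

## Derived statistics

**Relative frequencies** are per million tokens of the stored total:
`raw × 10⁶ / N`. A lemma is the pair (lemma, word class); its frequency sums
over all of its forms and feature strings.

**N-gram statistics** are token-weighted: each distinct form contributes its
form-level total frequency to the count of each bigram occurrence inside it
(multiplicity counted — *kukku* adds its frequency to `ku` twice), to its
initial trigram and to its final trigram (forms of length ≥ 3). A form's
`bigramfreq` is the arithmetic mean of its bigram counts; trigram *features*
are assigned only to forms of length ≥ 4, on the argument that for a
three-letter word the single trigram cannot meaningfully be both the first
and the last three letters. Length-3 forms still feed the *tables*, since
"how often does a word start with `aut`" is a property of the corpus, not of
the queried string. The same tables annotate nonwords, so pseudoword
stimuli are matched with exactly the same math as real words.

**Form ambiguity.** For a triple (lemma, pos, form) with frequency summed
over feature strings,

$$\mathrm{ambform} = 1 - \frac{freq(lemma, pos, form)}{freq(form)}.$$

It is the probability mass of the surface form belonging to *other*
readings; the complements `1 − ambform` across a form's readings always sum
to 1 (property-tested to 1e−9). Every feature row of the same triple carries
the same value.

**Lemma ambiguity.** A form counts as unambiguous iff its ambform is below a
threshold, default 0.01. The threshold exists because of parse noise: a
handful of mis-tagged tokens of an otherwise dedicated form should not mark
it ambiguous. Then

$$\mathrm{amblemma}(l, p) = \frac{\sum_{f} freq(l,p,f)\,
  \mathbf{1}[\mathrm{ambform}(l,p,f) \ge \theta]}{\mathrm{lemmafreq}(l,p)},$$

the frequency-weighted probability that a token of the lemma surfaces as an
ambiguous form. An uninflectable word whose single form is shared (a Finnish
interjection spelled like a verb form) scores exactly 1.

**Orthographic neighborhood.** Neighbors are distinct forms of the same
length at Hamming distance 1 (substitution only; length-changing edits never
count). Because low-frequency rows are disproportionately noise, candidates
are filtered: form frequency ≥ `autofreq` (default 10 000) is included
automatically; below `minfreq` (default 100) is excluded; in between, a
pluggable validity oracle decides. The defaults were tuned on a
multi-billion-token database and are *not* rescaled automatically for
smaller databases — they are configuration, not constants. The oracle
default accepts everything; `lexicon_oracle()` builds one from a word list,
standing in for a language-specific morphological analyzer. Both thresholds
apply to form-level totals (summed over readings), since neighborhood is a
property of the letter string. The implementation buckets forms by
single-position masks and is tested for exact agreement with an O(n²)
pairwise reference.

## The query language

Queries are conjunctions of parts separated by the word `and`; each part is
`key operator value`. The whole query is lowercased first, so queries are
case-insensitive. Operators: `=`, `!=`, `<`, `>` (numeric keys only for the
inequalities — the printed grammar has no `<=`/`>=`, and AND-only semantics
cannot emulate them), `in`/`not in` with comma-separated value lists, and
bare flags `compound`/`proper` with `not` negation. There is no `OR`, no
grouping and no regular expressions; set membership within one key is the
`in` operator. Values containing commas or the word `and` are unsupported —
the grammar has no quoting syntax.

Semantics worth stating precisely:

* Rows *lacking* a feature fail positive predicates on it and satisfy
  negative ones (`posspers not in 1,2,3` keeps words with no possessive
  suffix). Undefined numeric values (trigram features of short forms)
  behave the same way.
* `pos` predicates evaluate against `posx`, which folds auxiliaries into
  `VERB` — except when any value is `aux`, in which case the original
  column is used. So `pos = verb` includes auxiliaries and `pos = aux`
  selects exactly them.
* `start`, `end`, `mid` match the form by prefix, suffix and substring.
* Results order by descending form frequency, ties broken lexicographically
  by form, truncated at `max_rows` (default 10 000, configurable).

The key set is table-driven (`query_registry()`) so it can be amended in one
place. A deliberately naive row-by-row evaluator (`brute_force_query()`)
serves as an independent oracle; the suite compares the two on over a
thousand randomized queries.

## The synthetic corpus generator

Test corpora are exact multisets, not samples: a specification lists
(lemma, UPOS, form, feats) rows with multiplicities, and the generator emits
valid CoNLL-U where each row occurs exactly its multiplicity times. The seed
shuffles token order only, so every aggregate is seed-invariant — asserted
directly in the suite. Sentences default to 10 tokens with a flat dummy
head/deprel analysis, since frequency building never reads syntax. For
specifications carrying published table frequencies in the millions,
`lexicon_from_spec()` aggregates the multiset directly; its equality with
the generate–parse–build path is property-tested at small multiplicities.

What the generator does *not* emulate: Zipfian frequency structure,
sentence-level grammar, multiword-token or empty-node rows, and — most
importantly — realistic parser error patterns. Passing tests therefore
demonstrate correctness of the *computations* on controlled inputs, not
robustness of the *norms* against real-world tagging noise; the bundled
fixtures that copy published noisy-corpus rows (the *voi*/*voit* tables) are
the bridge between the two.

## Numerical and degenerate-input choices

* Ambiguity fractions and relative frequencies are kept at full double
  precision internally; rounding to the configured precision (default 3
  decimals) happens only at export/rendering.
* `relative_freq()` refuses a zero token total rather than returning `NaN`.
* An empty database cannot have aggregates computed; an empty corpus builds
  an empty database with total 0.
* Unknown n-grams count 0; annotating a string shorter than 2 is an error in
  `annotate_ngrams()` and a per-item skip (with warning) in
  `annotate_nonwords()`.
* Merging requires identical language codes; entry keys must be unique, and
  constructors verify that totals equal the sum of frequencies.
* Pruning is idempotent, and `applied_minfreq` records the strictest
  threshold applied.

## Problem sizes in the test suite

The randomized suites run at desk scale, chosen to finish in well under a
minute while still exercising every code path: 100 databases for the
ambiguity partition property, 25 databases × 40 queries (1 000 total, each
also rerun upper-cased) for oracle agreement, ≤ 200-form databases for the
neighborhood brute force, and 10-replicate loops for additivity,
conservation and idempotence properties. The worked-example fixtures carry
their published multi-million frequencies unchanged, since direct
aggregation makes database size irrelevant.

## Limitations

* Frequencies and tags inherit the source parser's errors; the ambiguity
  measures expose rather than remove them.
* No phonological variables (for orthographically transparent languages the
  spelling is the phonology, to a first approximation), no morphological
  family size (parsed data lacks derivational base information), no
  syllable statistics.
* The neighborhood validity oracle defaults to accepting everything; without
  a language resource, neighborhood counts in the mid-frequency band include
  noise forms.
* The query language is AND-only by design; disjunctions across *different*
  keys (e.g. `len< 10 OR len> 20`) cannot be expressed.
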