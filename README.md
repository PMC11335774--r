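# lexdb

`lexdb` builds disambiguated lexical-statistics databases from
dependency-parsed corpora (CoNLL-U / Universal Dependencies) and queries them
for psycholinguistic stimulus selection. It is aimed at researchers in
psycholinguistics, speech-language pathology and cognitive neuroscience who
need word-form and lemma norms — frequencies, length, sublexical n-gram
statistics, ambiguity, orthographic neighborhood — and a simple way to filter
words by those properties, without writing corpus-processing code themselves.
The defaults target Finnish, a morphologically rich language where one lemma
has thousands of potential surface forms, but any language with UD-parsed
text can be used.

## The database model

Every database row is uniquely keyed by the quadruple

```
(lemma, word class, surface form, core feature string)
```

where the core feature string is the canonical serialization of eleven
Universal Dependencies features: `Case`, `Number`, `Person`, possessor
`Person[psor]`/`Number[psor]`, `Clitic`, `Derivation`, `VerbForm`, `Mood`,
`Tense`, `Voice`. All text is lowercased, so frequencies are case-insensitive.
Tokens pass a noise filter before counting: every character in the language
charset, first character alphanumeric, at least one letter, length between 2
and 100. After pruning (minimum frequency, and removal of the `PUNCT`, `SYM`
and `X` classes) the statistics below are computed against the stored total
*N*:

* **Relative frequency** — `freq × 10⁶ / N` (per million tokens), for both
  forms and lemmas (a lemma is the pair lemma × word class).
* **N-gram statistics** — `initrigramfreq` and `fintrigramfreq` are the
  cumulative token frequencies of a form's first and last three letters
  (assigned only to forms of length ≥ 4); `bigramfreq` is the mean of the
  corpus-wide token-weighted counts of the form's adjacent letter pairs.
* **Form ambiguity** — for a triple (lemma, pos, form),
  `ambform = 1 − freq(lemma, pos, form) / freq(form)`: the probability that a
  token of this surface form belongs to a *different* lemma/word-class
  reading.
* **Lemma ambiguity** — `amblemma` is the frequency-weighted probability that
  a token of the lemma is realized as an ambiguous form, where a form counts
  as unambiguous iff its `ambform` is below 1 % (a noise allowance).
* **Orthographic neighborhood** — `hood` counts distinct same-length forms at
  Hamming distance 1 (one substituted letter), filtered for corpus noise:
  candidates with form frequency ≥ `autofreq` (10 000) are included
  automatically, those below `minfreq` (100) are excluded, and a pluggable
  validity oracle decides in between.

Results are filtered with a small AND-conjunctive query language
(`pos in NOUN,NUM and end in sta,na and len> 5 and not compound and
ambform< 0.95`), by word/lemma lists, or programmatically; nonword stimuli
can be annotated with the same n-gram statistics.

## Worked example

The bundled fixtures reproduce published frequency tables for the Finnish
form *voi*, which is overwhelmingly a present-tense form of the verb *voida*
('to be able to'), far more rarely the interjection ('oh') or the noun
('butter'):

```r
library(lexdb)
db <- lexicon_from_spec(builtin_fixture("table3_voi"))
db <- compute_aggregates(db)
evaluate_query(db, "form = voi and ambform > 0.9")[,
  .(lemma, pos, form, frequency, ambform = round(ambform, 3),
    amblemma = round(amblemma, 3))]
#>     lemma    pos   form frequency ambform amblemma
#> 1:    voi   INTJ    voi    750292   0.954        1
#> 2:    voi   NOUN    voi     52296   0.997        1
```

`ambform = 0.954` means 95.4 % of the tokens of the letter string *voi*
belong to readings other than the interjection; for the noun the share is
99.7 %. Both lemmas have `amblemma = 1.000`: within this database every one
of their forms is ambiguous, so neither lemma has a "safe" unambiguous form —
exactly the confound the measure is designed to expose when selecting
stimuli. Nonword (pseudoword) candidates can be annotated against the same
corpus:

```r
annotate_nonwords(c("voe", "vois"), db$ngrams)[,
  .(form, bigramfreq, initrigramfreq)]
#>      form bigramfreq initrigramfreq
#> 1:    voe    8233028             NA
#> 2:   vois   10977371       16466057
```

(`initrigramfreq` is `NA` for *voe*: trigram features require length ≥ 4.)

A command-line interface wraps the same functions:

```sh
inst/cli/lexdb build --db fi.lexdb corpus.conllu
inst/cli/lexdb query --db fi.lexdb --query "case = ine and len> 5" --out rows.csv
inst/cli/lexdb wordlist --db fi.lexdb --words stimuli.txt --mode form --out norms.tsv
```

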