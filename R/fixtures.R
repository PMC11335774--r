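#' Specify a synthetic corpus
#'
#' A corpus specification is an exact multiset of analyzed tokens: each row
#' gives one (lemma, word class, form, feature string) combination and how
#' many times it occurs. Emitted corpora reproduce the multiplicities exactly;
#' the seed only shuffles token order, so every aggregated statistic is
#' seed-invariant.
#'
#' @param rows A data frame with columns `lemma`, `upos`, `form`, `feats`
#'   (UD feature string, `"_"` for none) and `multiplicity` (>= 1).
#' @param sentence_length Tokens per emitted sentence (default 10).
#' @param seed Integer seed for shuffling only.
#' @return A `lexdb_corpus_spec` object.
#' @export
corpus_spec <- function(rows, sentence_length = 10L, seed = 1L) {
  rows <- as.data.table(rows)
  stopifnot(all(c("lemma", "upos", "form", "feats", "multiplicity")
                %in% names(rows)),
            all(rows$multiplicity >= 1), sentence_length >= 1)
  structure(list(rows = rows, sentence_length = as.integer(sentence_length),
                 seed = as.integer(seed)),
            class = "lexdb_corpus_spec")
}

#' Emit a corpus specification as CoNLL-U text
#'
#' Expands each specified row to its multiplicity, shuffles token order with
#' the spec's seed, and writes valid 10-column CoNLL-U with sentences of the
#' configured length. Head/deprel columns carry a flat dummy analysis (first
#' token `root`, the rest `dep`) since frequency building never reads them.
#' Aggregating the emitted text reproduces the specified multiset exactly,
#' regardless of seed. Intended for test corpora; multiplicities are
#' materialized, so keep totals desk-sized.
#'
#' @param spec A `lexdb_corpus_spec`.
#' @return Character vector of CoNLL-U lines.
#' @export
generate_conllu <- function(spec) {
  stopifnot(inherits(spec, "lexdb_corpus_spec"))
  r <- spec$rows
  idx <- rep(seq_len(nrow(r)), r$multiplicity)
  total <- length(idx)
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old_seed <- get(".Random.seed", envir = globalenv())
  set.seed(spec$seed)
  ord <- sample.int(total)
  if (had_seed) {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
  idx <- idx[ord]
  pos_in_sent <- ((seq_len(total) - 1L) %% spec$sentence_length) + 1L
  rows <- sprintf("%d\t%s\t%s\t%s\t_\t%s\t%d\t%s\t_\t_",
                  pos_in_sent, r$form[idx], r$lemma[idx], r$upos[idx],
                  r$feats[idx],
                  ifelse(pos_in_sent == 1L, 0L, 1L),
                  ifelse(pos_in_sent == 1L, "root", "dep"))
  n_sent <- ceiling(total / spec$sentence_length)
  out <- character(0)
  for (s in seq_len(n_sent)) {
    from <- (s - 1L) * spec$sentence_length + 1L
    to <- min(s * spec$sentence_length, total)
    out <- c(out, sprintf("# sent_id = %d", s), rows[from:to], "")
  }
  out
}

#' Build a lexicon directly from a corpus specification
#'
#' Aggregates the specified multiset without materializing token streams, so
#' specifications with multi-million multiplicities (e.g. frequencies copied
#' from published tables) build instantly. Equivalent by construction to
#' `build_lexicon(read_conllu(generate_conllu(spec)))`, which is property
#' tested at small multiplicities.
#'
#' @param spec A `lexdb_corpus_spec`.
#' @param ... Passed to [build_lexicon()] (charset, language, compound_sep).
#' @return A `lexdb`.
#' @export
lexicon_from_spec <- function(spec, ...) {
  stopifnot(inherits(spec, "lexdb_corpus_spec"))
  tok <- spec$rows[, .(form, lemma, upos, feats)]
  build_lexicon(tok, weights = spec$rows$multiplicity, ...)
}

#' Built-in worked-example fixtures
#'
#' Small corpus specifications reproducing published frequency tables for the
#' Finnish forms *silmäsi*, *voi* and *voit*:
#' \describe{
#'   \item{`table1_silmasi`}{The three analyses of *silmäsi* under the noun
#'     *silmä* (plural nominative 13464, singular genitive 4600, singular
#'     nominative 1307).}
#'   \item{`table3_voi`}{Five readings of the form *voi*: three feature rows
#'     of the verb *voida* (7810951, 4196751, 3655767), the interjection
#'     (750292) and the noun (52296).}
#'   \item{`table4_voi_forms`}{The six most frequent forms of the noun *voi*
#'     (64719, 52296, 17869, 13453, 5347, 3241).}
#'   \item{`table5_voit`}{Ten lemma/word-class readings of the form *voit*,
#'     illustrating parser noise.}
#' }
#'
#' @param name Fixture name.
#' @return A `lexdb_corpus_spec`.
#' @export
builtin_fixture <- function(name = c("table1_silmasi", "table3_voi",
                                     "table4_voi_forms", "table5_voit")) {
  name <- match.arg(name)
  rows <- switch(name,
    table1_silmasi = data.table(
      lemma = "silmä", upos = "NOUN", form = "silmäsi",
      feats = c("Case=Nom|Number=Plur", "Case=Gen|Number=Sing",
                "Case=Nom|Number=Sing"),
      multiplicity = c(13464, 4600, 1307)
    ),
    table3_voi = data.table(
      lemma = c("voida", "voida", "voida", "voi", "voi"),
      upos = c("VERB", "VERB", "VERB", "INTJ", "NOUN"),
      form = "voi",
      feats = c("Number=Sing|Person=3|Tense=Pres|VerbForm=Fin",
                "Number=Sing|Person=0|Tense=Pres|VerbForm=Fin",
                "Tense=Pres|VerbForm=Fin", "_", "Case=Nom|Number=Sing"),
      multiplicity = c(7810951, 4196751, 3655767, 750292, 52296)
    ),
    table4_voi_forms = data.table(
      lemma = "voi", upos = "NOUN",
      form = c("voita", "voi", "voin", "voissa", "voilla", "voista"),
      feats = c("Case=Par|Number=Sing", "Case=Nom|Number=Sing",
                "Case=Gen|Number=Sing", "Case=Ine|Number=Sing",
                "Case=Ade|Number=Sing", "Case=Ela|Number=Sing"),
      multiplicity = c(64719, 52296, 17869, 13453, 5347, 3241)
    ),
    table5_voit = data.table(
      lemma = c("voida", "voida", "voit", "voi", "voida", "voit", "voida",
                "voit", "voit", "voida"),
      upos = c("VERB", "NOUN", "NOUN", "NOUN", "PRON", "PROPN", "ADV",
               "VERB", "ADV", "ADJ"),
      form = "voit", feats = "_",
      multiplicity = c(3075975, 7425, 4288, 2700, 1711, 1218, 1045, 986,
                       786, 623)
    )
  )
  corpus_spec(rows)
}

#' The published ambform values accompanying `table4_voi_forms`
#'
#' Form ambiguity of the six noun-*voi* forms as measured on the full source
#' corpus (whose competing readings are not part of the fixture). Useful for
#' exercising [compute_amblemma()] with an externally supplied ambform table:
#' only *voissa* (0.002) falls below the 1% threshold.
#'
#' @return A `data.table` with columns `lemma`, `pos`, `form`, `ambform`.
#' @export
table4_published_ambform <- function() {
  data.table(
    lemma = "voi", pos = "NOUN",
    form = c("voita", "voi", "voin", "voissa", "voilla", "voista"),
    ambform = c(0.504, 0.997, 0.984, 0.002, 0.026, 0.033)
  )
}
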