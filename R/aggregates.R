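#' Compute all derived statistics for a database
#'
#' Attaches the full per-entry statistics table used by queries, wordlists and
#' exports: lemma frequency, per-million relative frequencies, n-gram
#' features, form ambiguity, lemma ambiguity and orthographic neighborhood.
#' Aggregates are always computed against the stored (post-pruning) data, so
#' relative values reflect exactly what is in the database.
#'
#' @param db A `lexdb` (built and pruned).
#' @param hood_params Neighborhood inclusion parameters
#'   ([neighborhood_params()]).
#' @param amblemma_threshold Ambform threshold below which a form counts as
#'   unambiguous for the amblemma computation (default 0.01).
#' @return The `lexdb` with `$stats` (one row per entry, columns in canonical
#'   result order) and `$ngrams` attached.
#' @export
compute_aggregates <- function(db, hood_params = neighborhood_params(),
                               amblemma_threshold = 0.01) {
  stopifnot(inherits(db, "lexdb"))
  if (db$total_tokens <= 0) stop("cannot compute aggregates on an empty database")
  st <- copy(db$entries)
  lf <- compute_lemma_freq(db)
  st[lf, `:=`(lemmafreq = i.lemmafreq), on = c("lemma", "pos")]
  st[, rellemmafreq := relative_freq(lemmafreq, db$total_tokens)]
  st[, relfrequency := relative_freq(frequency, db$total_tokens)]
  ngrams <- build_ngram_tables(db)
  ann <- annotate_ngrams(unique(st$form), ngrams)
  st[ann, `:=`(
    bigramfreq = i.bigramfreq, relbigramfreq = i.relbigramfreq,
    initrigramfreq = i.initrigramfreq, relinitrigramfreq = i.relinitrigramfreq,
    fintrigramfreq = i.fintrigramfreq, relfintrigramfreq = i.relfintrigramfreq
  ), on = "form"]
  af <- compute_ambform(db)
  st[af, ambform := i.ambform, on = c("lemma", "pos", "form")]
  al <- compute_amblemma(db, ambform = af, threshold = amblemma_threshold)
  st[al, amblemma := i.amblemma, on = c("lemma", "pos")]
  hd <- compute_neighborhood(db, hood_params)
  st[hd, hood := i.hood, on = "form"]
  setcolorder(st, RESULT_COLUMNS)
  db$stats <- st
  db$ngrams <- ngrams
  db
}
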