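#' Corpus-wide letter n-gram tables
#'
#' Builds token-weighted bigram, initial-trigram and final-trigram tables from
#' a (pruned) database. Each distinct surface form contributes its form-level
#' total frequency (summed over lemmas, word classes and feature strings) once
#' per occurrence of each bigram within it (multiplicity counted), once to the
#' initial-trigram count of its first three letters and once to the
#' final-trigram count of its last three letters (forms of length >= 3). The
#' scaling base for per-million values is the database token total.
#'
#' @param db A `lexdb`.
#' @return A `lexdb_ngrams` object: list with keyed `data.table`s `bigram`,
#'   `initial_trigram`, `final_trigram` (columns `gram`, `count`) and
#'   `scaling_base`.
#' @export
build_ngram_tables <- function(db) {
  stopifnot(inherits(db, "lexdb"))
  ff <- db$entries[, .(w = sum(frequency)), by = form]
  ff[, n_ := nchar(form)]
  grams <- function(tab) {
    tab <- tab[, .(count = sum(count)), by = gram]
    setkey(tab, gram)
    tab
  }
  big <- list()
  if (nrow(ff) > 0L) {
    maxn <- max(ff$n_)
    for (i in seq_len(max(maxn - 1L, 0L))) {
      sel <- ff$n_ > i
      if (!any(sel)) break
      big[[i]] <- data.table(gram = substr(ff$form[sel], i, i + 1L),
                             count = ff$w[sel])
    }
  }
  big <- if (length(big)) grams(rbindlist(big)) else
    grams(data.table(gram = character(), count = numeric()))
  tri <- ff[n_ >= 3L]
  init <- grams(data.table(gram = substr(tri$form, 1L, 3L), count = tri$w))
  fin <- grams(data.table(gram = substr(tri$form, tri$n_ - 2L, tri$n_),
                          count = tri$w))
  structure(
    list(bigram = big, initial_trigram = init, final_trigram = fin,
         scaling_base = db$total_tokens),
    class = "lexdb_ngrams"
  )
}

lookup_gram <- function(tab, keys) {
  out <- tab[match(keys, tab$gram), count]
  out[is.na(out)] <- 0
  out
}

#' Letter n-gram features for strings
#'
#' Computes the average bigram frequency and, for strings of at least four
#' characters, the initial and final trigram frequencies, against
#' corpus-wide tables. The bigram frequency is the arithmetic mean of the
#' table counts over the string's adjacent letter pairs; trigram features are
#' undefined (`NA`) below length four, where the whole string would be both
#' its first and last trigram. Relative values are per million tokens of the
#' table's scaling base. The strings need not exist in the database, so
#' nonword stimuli can be annotated with the same math as real forms.
#'
#' @param forms Character vector of strings, each at least 2 characters.
#' @param tables A `lexdb_ngrams` object from [build_ngram_tables()].
#' @return A `data.table` with columns `form`, `bigramfreq`, `relbigramfreq`,
#'   `initrigramfreq`, `relinitrigramfreq`, `fintrigramfreq`,
#'   `relfintrigramfreq`.
#' @export
annotate_ngrams <- function(forms, tables) {
  stopifnot(inherits(tables, "lexdb_ngrams"))
  n <- nchar(forms)
  if (any(n < 2L)) {
    stop(sprintf("strings shorter than 2 characters cannot be annotated: %s",
                 paste(forms[n < 2L], collapse = ", ")))
  }
  out <- data.table(form = forms, n_ = n)
  bsum <- numeric(length(forms))
  if (length(forms) > 0L) {
    for (i in seq_len(max(n) - 1L)) {
      sel <- n > i
      bsum[sel] <- bsum[sel] +
        lookup_gram(tables$bigram, substr(forms[sel], i, i + 1L))
    }
  }
  out[, bigramfreq := bsum / (n_ - 1L)]
  out[, initrigramfreq := ifelse(n_ >= 4L,
    lookup_gram(tables$initial_trigram, substr(form, 1L, 3L)), NA_real_)]
  out[, fintrigramfreq := ifelse(n_ >= 4L,
    lookup_gram(tables$final_trigram, substr(form, n_ - 2L, n_)), NA_real_)]
  base <- tables$scaling_base
  out[, `:=`(
    relbigramfreq = relative_freq(bigramfreq, base),
    relinitrigramfreq = relative_freq(initrigramfreq, base),
    relfintrigramfreq = relative_freq(fintrigramfreq, base)
  )]
  out[, n_ := NULL]
  setcolorder(out, c("form", "bigramfreq", "relbigramfreq", "initrigramfreq",
                     "relinitrigramfreq", "fintrigramfreq", "relfintrigramfreq"))
  out[]
}
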