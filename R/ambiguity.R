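#' Lemma frequencies
#'
#' A unique lemma is the combination of lemma and word class; its frequency is
#' the sum of entry frequencies over all of its surface forms and feature
#' strings.
#'
#' @param db A `lexdb`.
#' @return A `data.table` with columns `lemma`, `pos`, `lemmafreq`.
#' @export
compute_lemma_freq <- function(db) {
  stopifnot(inherits(db, "lexdb"))
  out <- db$entries[, .(lemmafreq = sum(frequency)), by = .(lemma, pos)]
  setkey(out, lemma, pos)
  out[]
}

#' Form ambiguity (ambform)
#'
#' For each (lemma, word class, form) triple, the weighted probability that a
#' token of the surface form belongs to a *different* lemma/word-class
#' reading: `1 - freq(lemma, pos, form) / freq(form)`, where the triple
#' frequency sums over feature strings and the form frequency sums over all
#' readings of the form. Every feature-string row of the same triple carries
#' the same value. 0 means the form is unambiguous; 1 means all of its
#' occurrences belong to other readings.
#'
#' @param db A `lexdb`.
#' @return A `data.table` with columns `lemma`, `pos`, `form`, `triplefreq`,
#'   `ambform`.
#' @export
compute_ambform <- function(db) {
  stopifnot(inherits(db, "lexdb"))
  tri <- db$entries[, .(triplefreq = sum(frequency)), by = .(lemma, pos, form)]
  tri[, formtotal := sum(triplefreq), by = form]
  tri[, ambform := 1 - triplefreq / formtotal]
  tri[, formtotal := NULL]
  setkey(tri, lemma, pos, form)
  tri[]
}

#' Lemma ambiguity (amblemma)
#'
#' For each (lemma, word class) pair, the frequency-weighted probability that
#' one of its tokens is realized as an ambiguous surface form. A form counts
#' as unambiguous iff its ambform is below the threshold (default 1%), an
#' allowance for parser noise: a handful of mis-tagged tokens should not make
#' an otherwise dedicated form ambiguous.
#'
#' @param db A `lexdb`.
#' @param ambform Optional ambform table as returned by [compute_ambform()]
#'   (columns `lemma`, `pos`, `form`, `ambform`). Defaults to computing it
#'   from `db`; supplying it allows scoring against ambiguity measured on a
#'   larger corpus.
#' @param threshold Ambform value at or above which a form counts as
#'   ambiguous; in (0, 1), default 0.01.
#' @return A `data.table` with columns `lemma`, `pos`, `amblemma`.
#' @export
compute_amblemma <- function(db, ambform = NULL, threshold = 0.01) {
  stopifnot(inherits(db, "lexdb"), threshold > 0, threshold < 1)
  if (is.null(ambform)) ambform <- compute_ambform(db)
  tri <- db$entries[, .(triplefreq = sum(frequency)), by = .(lemma, pos, form)]
  tri <- merge(tri, ambform[, .(lemma, pos, form, ambform)],
               by = c("lemma", "pos", "form"), all.x = TRUE)
  if (anyNA(tri$ambform)) {
    stop("ambform table does not cover every (lemma, pos, form) triple")
  }
  out <- tri[, .(amblemma = sum(triplefreq * (ambform >= threshold)) /
                   sum(triplefreq)),
             by = .(lemma, pos)]
  setkey(out, lemma, pos)
  out[]
}
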