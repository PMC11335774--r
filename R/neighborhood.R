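#' Neighborhood inclusion parameters
#'
#' Controls which candidate forms may count as orthographic neighbors. A
#' candidate with form-level frequency at or above `autofreq` is included
#' automatically; one below `minfreq` is excluded; in between, the validity
#' oracle decides. The oracle is a pluggable predicate (a function taking a
#' character vector and returning a logical vector) standing in for a
#' language-specific morphological analyzer or spelling dictionary; the
#' default accepts everything.
#'
#' @param autofreq Automatic-inclusion frequency (default 10000).
#' @param minfreq Exclusion frequency floor (default 100); must be
#'   `<= autofreq`.
#' @param oracle `NULL` (accept all) or a vectorized predicate.
#' @return A `lexdb_hood_params` list.
#' @export
neighborhood_params <- function(autofreq = 10000, minfreq = 100, oracle = NULL) {
  stopifnot(minfreq <= autofreq, is.null(oracle) || is.function(oracle))
  structure(list(autofreq = autofreq, minfreq = minfreq, oracle = oracle),
            class = "lexdb_hood_params")
}

#' Validity oracle from a word list
#'
#' Builds a neighborhood validity oracle that accepts exactly the words in a
#' user-supplied lexicon (a plain-text file or character vector, one word per
#' line, lowercased on load).
#'
#' @param words Character vector of valid words, or a path to a word file.
#' @return A vectorized predicate suitable for [neighborhood_params()].
#' @export
lexicon_oracle <- function(words) {
  if (length(words) == 1L && file.exists(words)) words <- load_wordlist(words)
  words <- unique(tolower(words))
  function(x) tolower(x) %in% words
}

#' Orthographic neighborhood size
#'
#' The neighborhood of a form is the set of *other* distinct forms in the
#' database at Hamming distance 1: same length, exactly one substituted
#' character. Because parsed web corpora are noisy, candidate neighbors are
#' filtered by form-level frequency and the validity oracle (see
#' [neighborhood_params()]); every form in the database still receives a
#' count, whether or not it passes the filter itself.
#'
#' @param db A `lexdb`.
#' @param params A `lexdb_hood_params` object.
#' @return A `data.table` with columns `form`, `hood`.
#' @export
compute_neighborhood <- function(db, params = neighborhood_params()) {
  stopifnot(inherits(db, "lexdb"), inherits(params, "lexdb_hood_params"))
  ff <- db$entries[, .(w = sum(frequency)), by = form]
  if (nrow(ff) == 0L) return(data.table(form = character(), hood = integer()))
  inc <- ff$w >= params$autofreq
  mid <- !inc & ff$w >= params$minfreq
  if (any(mid)) {
    if (is.null(params$oracle)) {
      inc[mid] <- TRUE
    } else {
      ok <- params$oracle(ff$form[mid])
      stopifnot(is.logical(ok), length(ok) == sum(mid))
      inc[mid] <- ok
    }
  }
  forms <- ff$form
  n <- nchar(forms)
  # bucket by masking one position: two forms share a masked key iff they are
  # identical outside that position
  mask_keys <- function(f, ln) {
    if (length(f) == 0L) {
      return(data.table(key_ = character(), form = character()))
    }
    keys <- vector("list", max(ln))
    for (i in seq_len(max(ln))) {
      sel <- ln >= i
      keys[[i]] <- data.table(
        key_ = paste0(ln[sel], ":", i, ":", substr(f[sel], 1L, i - 1L), "\r",
                      substr(f[sel], i + 1L, ln[sel])),
        form = f[sel]
      )
    }
    rbindlist(keys)
  }
  cand <- mask_keys(forms[inc], n[inc])
  bucket <- cand[, .(n_ = .N), by = key_]
  setkey(bucket, key_)
  mine <- mask_keys(forms, n)
  mine[, n_ := bucket[match(mine$key_, bucket$key_), n_]]
  mine[is.na(n_), n_ := 0L]
  hood <- mine[, .(hood = sum(n_)), by = form]
  # a form that passes the filter occupies one slot in each of its own buckets
  hood <- hood[match(forms, form)]
  hood[, hood := hood - ifelse(inc, n, 0L)]
  setkey(hood, form)
  hood[]
}
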