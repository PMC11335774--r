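#' Load a word list
#'
#' Reads a plain UTF-8 word list, one token per line. Lines are trimmed and
#' lowercased, empty lines dropped; order and duplicates are preserved.
#'
#' @param input File path, connection, or character vector of lines.
#' @return Character vector of words.
#' @export
load_wordlist <- function(input) {
  if (inherits(input, "connection")) {
    lines <- readLines(input, encoding = "UTF-8", warn = FALSE)
  } else if (is.character(input) && length(input) == 1L &&
             !grepl("\n", input) && file.exists(input)) {
    lines <- readLines(input, encoding = "UTF-8", warn = FALSE)
  } else if (is.character(input)) {
    lines <- as.character(unlist(strsplit(input, "\n", fixed = TRUE),
                                 use.names = FALSE))
  } else {
    stop("`input` must be a file path, connection or character vector")
  }
  if (length(lines) && any(!validUTF8(lines))) {
    stop("word list is not valid UTF-8")
  }
  words <- tolower(trimws(lines))
  words[words != ""]
}

#' Fetch database rows for a word or lemma list
#'
#' Looks up every statistics row whose surface form (mode `"form"`) or lemma
#' (mode `"lemma"`) appears in the list. Inputs with no database row are
#' reported as misses, so stimulus builders know which candidates lack norms.
#' The returned rows are an ordinary statistics table, further filterable with
#' [evaluate_query()] exactly like free-search results.
#'
#' @param db A `lexdb` with aggregates computed.
#' @param words Character vector of words (lowercased; see
#'   [load_wordlist()]).
#' @param mode `"form"` or `"lemma"`.
#' @return A `lexdb_wordlist` list with elements `rows` (result rows),
#'   `misses` (unmatched inputs, duplicates collapsed) and `mode`.
#' @export
lookup_wordlist <- function(db, words, mode = c("form", "lemma")) {
  mode <- match.arg(mode)
  stopifnot(inherits(db, "lexdb"))
  if (is.null(db$stats)) stop("aggregates not computed; run compute_aggregates() first")
  words <- tolower(words)
  col <- db$stats[[mode]]
  rows <- db$stats[col %in% words]
  setorderv(rows, c("frequency", "form"), order = c(-1L, 1L))
  structure(
    list(rows = rows, misses = setdiff(unique(words), unique(col)),
         mode = mode),
    class = "lexdb_wordlist"
  )
}

#' N-gram statistics for nonwords
#'
#' Annotates arbitrary letter strings -- typically pseudoword candidates for a
#' lexical decision task -- with the same average-bigram and initial/final
#' trigram statistics stored for real forms, computed against the corpus
#' n-gram tables. Strings shorter than 2 characters cannot carry bigram
#' statistics; they are returned with missing values and reported in the
#' `skipped` attribute while the remaining items are still processed.
#'
#' @param strings Character vector of (non)words, lowercased on input.
#' @param tables A `lexdb_ngrams` object (e.g. `db$ngrams` after
#'   [compute_aggregates()]).
#' @return A `data.table` as from [annotate_ngrams()], one row per input (in
#'   order), with attribute `skipped` listing too-short inputs.
#' @export
annotate_nonwords <- function(strings, tables) {
  strings <- tolower(strings)
  ok <- nchar(strings) >= 2L
  out <- data.table(form = strings, bigramfreq = NA_real_,
                    relbigramfreq = NA_real_, initrigramfreq = NA_real_,
                    relinitrigramfreq = NA_real_, fintrigramfreq = NA_real_,
                    relfintrigramfreq = NA_real_)
  if (any(ok)) {
    ann <- annotate_ngrams(strings[ok], tables)
    for (col in setdiff(names(ann), "form")) {
      set(out, i = which(ok), j = col, value = ann[[col]])
    }
  }
  if (any(!ok)) {
    warning(sprintf("skipped %d string(s) shorter than 2 characters",
                    sum(!ok)))
  }
  setattr(out, "skipped", strings[!ok])
  out[]
}
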