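#' Read a CoNLL-U corpus into a token table
#'
#' Parses CoNLL-U (10 tab-separated columns, UTF-8) and returns one row per
#' syntactic word. Multiword-token range rows (ID like `4-5`) and empty-node
#' rows (ID like `5.1`) are skipped, as are comment lines and blank
#' sentence separators. Forms and lemmas are lowercased on input so that all
#' downstream frequencies are case-insensitive.
#'
#' @param input Path to a CoNLL-U file, a connection, or a character vector of
#'   lines (useful for in-memory corpora).
#' @return A `data.table` with columns `form`, `lemma`, `upos` and `feats`
#'   (the raw UD feature string, `"_"` when empty).
#' @export
#' @examples
#' txt <- "1\tAutossa\tauto\tNOUN\t_\tCase=Ine|Number=Sing\t0\troot\t_\t_"
#' read_conllu(txt)
read_conllu <- function(input) {
  if (inherits(input, "connection")) {
    lines <- readLines(input, encoding = "UTF-8", warn = FALSE)
  } else if (is.character(input) && length(input) == 1L &&
             !grepl("\t|\n", input) && file.exists(input)) {
    lines <- readLines(input, encoding = "UTF-8", warn = FALSE)
  } else if (is.character(input)) {
    lines <- as.character(unlist(strsplit(input, "\n", fixed = TRUE),
                                 use.names = FALSE))
  } else {
    stop("`input` must be a file path, connection or character vector")
  }
  keep <- !(lines == "" | startsWith(lines, "#"))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(data.table(form = character(), lemma = character(),
                      upos = character(), feats = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 10L)) {
    bad <- which(nf != 10L)[1L]
    stop(sprintf(
      "malformed CoNLL-U row at line %d: expected 10 tab-separated columns, got %d",
      lineno[bad], nf[bad]
    ), call. = FALSE)
  }
  m <- matrix(unlist(parts, use.names = FALSE), ncol = 10L, byrow = TRUE)
  # keep only plain syntactic-word rows: integer IDs
  word <- grepl("^[0-9]+$", m[, 1L])
  data.table(
    form  = tolower(m[word, 2L]),
    lemma = tolower(m[word, 3L]),
    upos  = m[word, 4L],
    feats = m[word, 6L]
  )
}

#' Token acceptance filter
#'
#' Decides whether a token passes the noise pre-filter applied while building
#' a database. A string is accepted iff every character matches the language
#' charset, the first character is alphanumeric, at least one character is a
#' letter, and the length is between 2 and 100 characters. Both the surface
#' form and the lemma must pass for the token to be counted.
#'
#' @param form Character vector of lowercased surface forms.
#' @param lemma Optional character vector of lowercased lemmas (same length);
#'   when supplied both must pass.
#' @param charset A regex character class matching every permitted character
#'   (default: Finnish letters, digits, hyphen and apostrophe).
#' @param letters A regex character class of what counts as a letter.
#' @return Logical vector.
#' @export
accept_token <- function(form, lemma = NULL, charset = FI_CHARSET,
                         letters = paste0("[", FI_LETTERS, "]")) {
  ok <- accept_string(form, charset, letters)
  if (!is.null(lemma)) ok <- ok & accept_string(lemma, charset, letters)
  ok
}

accept_string <- function(x, charset = FI_CHARSET,
                          letters = paste0("[", FI_LETTERS, "]")) {
  n <- nchar(x)
  alnum <- sub("\\]$", "0-9]", letters)  # letters plus digits
  n >= 2L & n <= 100L &
    !grepl(paste0("[^", substr(charset, 2L, nchar(charset))), x) &
    grepl(paste0("^", alnum), x) &
    grepl(letters, x)
}

#' Project UD features onto the core feature set
#'
#' Keeps only the eleven disambiguating ("core") morphological features --
#' case, number, person, possessor person/number, clitic, derivation, verb
#' form, mood, tense and voice -- and serializes them canonically:
#' `Key=Value` pairs joined by `|` in a fixed key order, with the empty set
#' serialized as `"_"`. Dropped features (Degree, Polarity, style and other
#' extended features) never influence database keys.
#'
#' @param feats Character vector of raw UD feature strings (`"_"` or `""`
#'   for none).
#' @return A `data.table` with column `feats` (canonical serialization) plus
#'   one lowercase-named column per core feature (`""` when absent).
#' @export
#' @examples
#' project_core_features("Case=Nom|Degree=Pos|Number=Plur")
project_core_features <- function(feats) {
  n <- length(feats)
  out <- data.table(feats = rep(EMPTY_FEATS, n))
  for (col in CORE_FEATURE_KEYS) set(out, j = col, value = rep("", n))
  if (n == 0L) return(out[])
  todo <- !(is.na(feats) | feats == "" | feats == EMPTY_FEATS)
  if (any(todo)) {
    idx <- which(todo)
    pairs <- strsplit(feats[idx], "|", fixed = TRUE)
    flat <- unlist(pairs, use.names = FALSE)
    row <- rep(idx, lengths(pairs))
    eq <- regexpr("=", flat, fixed = TRUE)
    keys <- substr(flat, 1L, eq - 1L)
    vals <- substr(flat, eq + 1L, nchar(flat))
    known <- keys %in% names(CORE_FEATURE_KEYS)
    keys <- keys[known]; vals <- vals[known]; row <- row[known]
    for (k in unique(keys)) {
      sel <- keys == k
      set(out, i = row[sel], j = CORE_FEATURE_KEYS[[k]], value = vals[sel])
    }
    # canonical serialization in fixed key order
    ser <- rep("", n)
    for (k in names(CORE_FEATURE_KEYS)) {
      v <- out[[CORE_FEATURE_KEYS[[k]]]]
      has <- v != ""
      piece <- paste0(k, "=", v[has])
      ser[has] <- ifelse(ser[has] == "", piece, paste0(ser[has], "|", piece))
    }
    out[ser != "", feats := ser[ser != ""]]
  }
  out[]
}

#' Build a lexicon database from a token stream
#'
#' Applies the token filter, projects core features and aggregates
#' frequencies. Entries are uniquely keyed by (lemma, word class, surface
#' form, core feature string); tokens differing only in a dropped feature
#' merge into one entry. Compounds are flagged by the compound separator in
#' the lemma (Finnish UD convention `#`), which is then stripped so stored
#' lemmas are plain orthographic strings. `totalTokens` equals the number of
#' accepted tokens.
#'
#' @param tokens A token table as returned by [read_conllu()].
#' @param charset Permitted-character class for the token filter.
#' @param language Language code stored in the database metadata.
#' @param compound_sep Character marking compound boundaries in lemmas.
#' @param weights Optional integer vector of per-row multiplicities (used by
#'   the fixture generator to aggregate weighted specs without expansion).
#' @return A `lexdb` object.
#' @export
build_lexicon <- function(tokens, charset = FI_CHARSET, language = "fi",
                          compound_sep = "#", weights = NULL) {
  stopifnot(is.data.frame(tokens))
  tok <- as.data.table(tokens)
  if (is.null(weights)) weights <- rep(1L, nrow(tok))
  stopifnot(length(weights) == nrow(tok), all(weights >= 1))
  if (nrow(tok) == 0L) {
    return(new_lexicon(empty_entries(), total_tokens = 0L, language = language))
  }
  frm <- tolower(tok$form)
  lem <- tolower(tok$lemma)
  comp <- grepl(compound_sep, lem, fixed = TRUE)
  lem <- gsub(compound_sep, "", lem, fixed = TRUE)
  ok <- accept_token(frm, lem, charset = charset)
  if (!any(ok)) {
    return(new_lexicon(empty_entries(), total_tokens = 0L, language = language))
  }
  fc <- project_core_features(tok$feats[ok])
  ent <- data.table(
    lemma = lem[ok], pos = tok$upos[ok], form = frm[ok],
    compound = comp[ok], w = as.numeric(weights[ok])
  )
  ent <- cbind(ent, fc)
  ent <- ent[, .(frequency = sum(w), compound = compound[1L]),
             by = c("lemma", "pos", "form", "feats", unname(CORE_FEATURE_KEYS))]
  ent[, len := nchar(form)]
  ent[, posx := compute_posx(pos)]
  ent[, proper := pos == "PROPN"]
  setcolorder(ent, entry_columns())
  new_lexicon(ent, total_tokens = sum(ent$frequency), language = language)
}

#' Query-time word class
#'
#' Regular and auxiliary verbs are combined under a single tag for most
#' queries: `AUX` maps to `VERB`, every other tag maps to itself.
#'
#' @param pos Character vector of UD word-class tags.
#' @return Character vector of the same length.
#' @export
compute_posx <- function(pos) {
  ifelse(pos == "AUX", "VERB", pos)
}
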