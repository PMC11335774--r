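entry_columns <- function() {
  c("lemma", "pos", "posx", "form", "feats", unname(CORE_FEATURE_KEYS),
    "frequency", "len", "compound", "proper")
}

empty_entries <- function() {
  ent <- data.table(
    lemma = character(), pos = character(), posx = character(),
    form = character(), feats = character()
  )
  for (col in CORE_FEATURE_KEYS) set(ent, j = col, value = character())
  ent[, `:=`(frequency = numeric(), len = integer(),
             compound = logical(), proper = logical())]
  ent[]
}

#' Construct a lexicon database object
#'
#' Low-level constructor; most users build databases with [build_lexicon()]
#' or [lexicon_from_spec()]. Entries must be unique on the
#' (lemma, pos, form, feats) quadruple and `total_tokens` must equal the sum
#' of entry frequencies.
#'
#' @param entries Entry table (see [build_lexicon()] for the schema).
#' @param total_tokens Number of tokens the stored entries represent.
#' @param language Language code.
#' @param applied_minfreq Minimum frequency already applied by pruning.
#' @param metadata Named list of additional metadata.
#' @return An object of class `lexdb`: a list with elements `entries`,
#'   `total_tokens`, `language`, `applied_minfreq`, `metadata`, and (after
#'   [compute_aggregates()]) `stats` and `ngrams`.
#' @export
new_lexicon <- function(entries, total_tokens, language = "fi",
                        applied_minfreq = 0, metadata = list()) {
  entries <- as.data.table(entries)
  stopifnot(all(entry_columns() %in% names(entries)))
  if (anyDuplicated(entries, by = c("lemma", "pos", "form", "feats")) > 0L) {
    stop("entries are not unique on (lemma, pos, form, feats)")
  }
  if (abs(sum(entries$frequency) - total_tokens) > 1e-9) {
    stop("total_tokens must equal the sum of entry frequencies")
  }
  setkeyv(entries, c("lemma", "pos", "form", "feats"))
  structure(
    list(entries = entries, total_tokens = total_tokens, language = language,
         applied_minfreq = applied_minfreq, metadata = metadata,
         stats = NULL, ngrams = NULL),
    class = "lexdb"
  )
}

#' @export
print.lexdb <- function(x, ...) {
  cat(sprintf(
    "<lexdb> language=%s entries=%d totalTokens=%.0f appliedMinFreq=%s aggregates=%s\n",
    x$language, nrow(x$entries), x$total_tokens, format(x$applied_minfreq),
    if (is.null(x$stats)) "no" else "yes"
  ))
  invisible(x)
}

#' Merge two lexicon databases
#'
#' Takes the union of entry keys; when a (lemma, pos, form, feats) row exists
#' in both databases the frequencies are summed. Database token totals also
#' sum, so building from a concatenated corpus and merging per-file builds
#' give identical results.
#'
#' @param a,b `lexdb` objects sharing the same language.
#' @return A merged `lexdb`. Derived aggregates are dropped and must be
#'   recomputed.
#' @export
merge_lexicons <- function(a, b) {
  stopifnot(inherits(a, "lexdb"), inherits(b, "lexdb"))
  if (!identical(a$language, b$language)) {
    stop(sprintf("language mismatch: '%s' vs '%s'", a$language, b$language))
  }
  ent <- rbind(a$entries, b$entries)
  ent <- ent[, .(frequency = sum(frequency), posx = posx[1L], len = len[1L],
                 compound = compound[1L], proper = proper[1L]),
             by = c("lemma", "pos", "form", "feats", unname(CORE_FEATURE_KEYS))]
  setcolorder(ent, entry_columns())
  new_lexicon(ent, total_tokens = a$total_tokens + b$total_tokens,
              language = a$language)
}

#' Prune a lexicon database
#'
#' Removes entries below a minimum frequency and entries whose word class is
#' excluded (by default punctuation, symbols and unidentified classes).
#' `totalTokens` is recomputed over the survivors, so relative frequencies
#' reflect the stored data. All derived statistics must be (re)computed after
#' pruning; any previously attached aggregates are dropped.
#'
#' @param db A `lexdb`.
#' @param minfreq Minimum entry frequency to keep (>= 0).
#' @param excluded_pos Word classes to drop regardless of frequency.
#' @return A pruned `lexdb` with `applied_minfreq` recorded.
#' @export
prune_lexicon <- function(db, minfreq = 0, excluded_pos = DEFAULT_EXCLUDED_POS) {
  stopifnot(inherits(db, "lexdb"), minfreq >= 0)
  ent <- db$entries[frequency >= minfreq & !(pos %in% excluded_pos)]
  new_lexicon(ent, total_tokens = sum(ent$frequency), language = db$language,
              applied_minfreq = max(minfreq, db$applied_minfreq),
              metadata = db$metadata)
}

#' Per-million relative frequency
#'
#' @param raw Raw count(s).
#' @param total_tokens Token total of the (pruned) database; must be > 0.
#' @return `raw * 1e6 / total_tokens`.
#' @export
relative_freq <- function(raw, total_tokens) {
  if (length(total_tokens) != 1L || is.na(total_tokens) || total_tokens <= 0) {
    stop("database has no tokens: relative frequencies are undefined")
  }
  raw * 1e6 / total_tokens
}

#' Save and load a lexicon database
#'
#' The on-disk store is a single UTF-8 file: `#key<TAB>value` metadata header
#' lines followed by a tab-separated entry table. The round trip is lossless
#' for entries and metadata; derived aggregates are recomputed on demand.
#'
#' @param db A `lexdb`.
#' @param path File path.
#' @return `save_lexicon` returns `path` invisibly; `load_lexicon` returns a
#'   `lexdb`.
#' @export
save_lexicon <- function(db, path) {
  stopifnot(inherits(db, "lexdb"))
  hdr <- c(
    "#lexdb\t1",
    paste0("#language\t", db$language),
    paste0("#totaltokens\t", format(db$total_tokens, scientific = FALSE)),
    paste0("#appliedminfreq\t", format(db$applied_minfreq, scientific = FALSE))
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(hdr, con, useBytes = TRUE)
  close(con); on.exit()
  fwrite(db$entries, path, sep = "\t", append = TRUE, col.names = TRUE,
         quote = FALSE)
  invisible(path)
}

#' @rdname save_lexicon
#' @export
load_lexicon <- function(path) {
  if (!file.exists(path)) stop(sprintf("database file not found: %s", path))
  lines <- readLines(path, n = 10L, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0L || lines[1L] != "#lexdb\t1") {
    stop(sprintf("not a lexdb database file: %s", path))
  }
  hdr <- lines[startsWith(lines, "#")]
  kv <- strsplit(sub("^#", "", hdr), "\t", fixed = TRUE)
  meta <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  ent <- fread(path, sep = "\t", skip = length(hdr), header = TRUE,
               encoding = "UTF-8", colClasses = list(
                 character = c("lemma", "pos", "posx", "form", "feats",
                               unname(CORE_FEATURE_KEYS))))
  for (col in c("lemma", "pos", "posx", "form", "feats", unname(CORE_FEATURE_KEYS))) {
    if (!col %in% names(ent)) set(ent, j = col, value = character(nrow(ent)))
  }
  new_lexicon(ent, total_tokens = as.numeric(meta[["totaltokens"]]),
              language = meta[["language"]],
              applied_minfreq = as.numeric(meta[["appliedminfreq"]]))
}
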