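#' The query key registry
#'
#' Table of every key usable in the query mini-language: its value kind
#' (`text`, `number`, `flag`, `feature`, `pos`), the statistics column it
#' matches, and the match style for text keys (`exact`, `prefix`, `suffix`,
#' `substring`). The registry is table-driven so the key set can be amended
#' without touching the parser.
#'
#' @return A `data.table` with columns `key`, `kind`, `column`, `match`.
#' @export
query_registry <- function() {
  feat <- unname(CORE_FEATURE_KEYS)
  num <- c("len", "frequency", "relfrequency", "lemmafreq", "rellemmafreq",
           "bigramfreq", "relbigramfreq", "initrigramfreq",
           "relinitrigramfreq", "fintrigramfreq", "relfintrigramfreq",
           "ambform", "amblemma", "hood")
  rbindlist(list(
    data.table(qkey = c("form", "lemma"), kind = "text",
               column = c("form", "lemma"), match = "exact"),
    data.table(qkey = c("start", "end", "mid"), kind = "text", column = "form",
               match = c("prefix", "suffix", "substring")),
    data.table(qkey = num, kind = "number", column = num, match = "exact"),
    data.table(qkey = "pos", kind = "pos", column = "posx", match = "exact"),
    data.table(qkey = feat, kind = "feature", column = feat, match = "exact"),
    data.table(qkey = c("compound", "proper"), kind = "flag",
               column = c("compound", "proper"), match = "exact")
  ))[, .(key = qkey, kind, column, match)]
}

#' Split a query string into parts
#'
#' The whole query is lowercased first (queries are case-insensitive:
#' `case = Ine` and `case = ine` are equivalent) and then split on the
#' standalone word `and`. Operator symbols need not be surrounded by
#' whitespace (`len> 5` parses the same as `len > 5`).
#'
#' @param query_text Query string.
#' @return Character vector of trimmed lowercased parts.
#' @export
tokenize_query <- function(query_text) {
  stopifnot(is.character(query_text), length(query_text) == 1L)
  q <- tolower(trimws(query_text))
  if (q == "") stop("empty query", call. = FALSE)
  parts <- trimws(strsplit(q, "\\band\\b", perl = TRUE)[[1L]])
  if (grepl("\\band\\s*$", q, perl = TRUE)) parts <- c(parts, "")
  if (any(parts == "") || length(parts) == 0L) {
    stop("malformed query: empty query part around 'and'", call. = FALSE)
  }
  parts
}

#' Parse a query string
#'
#' Compiles the AND-conjunctive mini-language into a list of typed
#' predicates. Supported forms per part: `key = value`, `key != value`,
#' `key < value`, `key > value` (numeric keys only for `<`/`>`),
#' `key in v1,v2,...`, `key not in v1,v2,...`, and the bare flags
#' `compound` / `proper` with their negations `not compound` / `not proper`.
#' There is no OR, no grouping and no regular-expression matching; set
#' membership within one key is expressed with `in`.
#'
#' @param query_text Query string.
#' @param registry Key registry (defaults to [query_registry()]).
#' @return A `lexdb_query` object: list of predicates, each with `key`, `op`
#'   (`eq`, `neq`, `lt`, `gt`, `in`, `not_in`, `flag`, `not_flag`) and
#'   `values`.
#' @export
parse_query <- function(query_text, registry = query_registry()) {
  parts <- tokenize_query(query_text)
  preds <- lapply(parts, parse_part, registry = registry)
  structure(list(predicates = preds, text = query_text), class = "lexdb_query")
}

parse_part <- function(part, registry) {
  if (grepl("\\bor\\b", part, perl = TRUE)) {
    stop(sprintf("unsupported operator OR in query part '%s' (use 'key in v1,v2' for sets)",
                 part), call. = FALSE)
  }
  reg_row <- function(key) {
    sel <- registry[["key"]] == key
    r <- registry[which(sel)]
    if (nrow(r) == 0L) {
      stop(sprintf("unknown query key '%s'", key), call. = FALSE)
    }
    r
  }
  mk <- function(key, op, values = character()) {
    r <- reg_row(key)
    if (op %in% c("flag", "not_flag") && r$kind != "flag") {
      stop(sprintf("key '%s' is not a flag", key), call. = FALSE)
    }
    if (op %in% c("lt", "gt") && r$kind != "number") {
      stop(sprintf("operator '%s' requires a numeric key, not '%s'",
                   if (op == "lt") "<" else ">", key), call. = FALSE)
    }
    if (r$kind == "flag" && !op %in% c("flag", "not_flag")) {
      stop(sprintf("flag key '%s' takes no value", key), call. = FALSE)
    }
    if (r$kind == "number" && length(values)) {
      nv <- suppressWarnings(as.numeric(values))
      if (anyNA(nv)) {
        stop(sprintf("non-numeric value for numeric key '%s'", key),
             call. = FALSE)
      }
      values <- nv
    }
    list(key = key, op = op, values = values,
         kind = r$kind, column = r$column, match = r$match)
  }
  split_values <- function(txt, part) {
    v <- trimws(strsplit(txt, ",", fixed = TRUE)[[1L]])
    if (length(v) == 0L || any(v == "")) {
      stop(sprintf("malformed value list in query part '%s'", part),
           call. = FALSE)
    }
    v
  }
  if (grepl("^[a-zåäöšž_]+$", part)) return(mk(part, "flag"))
  m <- regmatches(part, regexec("^not\\s+([a-zåäöšž_]+)$", part, perl = TRUE))[[1L]]
  if (length(m)) return(mk(m[2L], "not_flag"))
  m <- regmatches(part, regexec("^(\\S+)\\s+not\\s+in\\s+(.+)$", part, perl = TRUE))[[1L]]
  if (length(m)) return(mk(m[2L], "not_in", split_values(m[3L], part)))
  m <- regmatches(part, regexec("^(\\S+)\\s+in\\s+(.+)$", part, perl = TRUE))[[1L]]
  if (length(m)) return(mk(m[2L], "in", split_values(m[3L], part)))
  m <- regmatches(part, regexec("^\\s*([^!=<>\\s]+)\\s*(!=|=|<|>)\\s*(.+)$",
                                part, perl = TRUE))[[1L]]
  if (length(m)) {
    op <- c("=" = "eq", "!=" = "neq", "<" = "lt", ">" = "gt")[[m[3L]]]
    val <- trimws(m[4L])
    if (val == "") stop(sprintf("missing value in query part '%s'", part),
                        call. = FALSE)
    return(mk(m[2L], op, val))
  }
  stop(sprintf("malformed query part '%s'", part), call. = FALSE)
}

# Logical mask of rows matching one predicate. Rows lacking a feature fail
# positive predicates on that feature and satisfy negative ones, so e.g.
# "posspers not in 1,2,3" keeps words with no possessive suffix at all.
predicate_mask <- function(stats, p) {
  op <- p$op
  if (p$kind == "flag") {
    col <- stats[[p$column]]
    return(if (op == "flag") col else !col)
  }
  if (p$kind == "number") {
    col <- stats[[p$column]]
    v <- p$values[1L]
    m <- switch(op,
      eq = col == v,
      neq = col != v,
      lt = col < v,
      gt = col > v,
      `in` = col %in% p$values,
      not_in = !(col %in% p$values)
    )
    # undefined values (e.g. trigram features of short forms) fail positive
    # operators and pass negative ones
    m[is.na(m)] <- op %in% c("neq", "not_in")
    return(m)
  }
  if (p$kind == "pos") {
    use_pos <- any(p$values == "aux")
    col <- tolower(if (use_pos) stats$pos else stats$posx)
  } else {
    col <- tolower(stats[[p$column]])
  }
  if (p$kind %in% c("pos", "feature") || p$match == "exact") {
    m <- switch(op,
      eq = col == p$values[1L],
      neq = col != p$values[1L],
      `in` = col %in% p$values,
      not_in = !(col %in% p$values),
      stop(sprintf("operator not supported for key '%s'", p$key), call. = FALSE)
    )
    return(m)
  }
  # prefix / suffix / substring matching on the form
  one <- function(v) switch(p$match,
    prefix = startsWith(col, v),
    suffix = endsWith(col, v),
    substring = grepl(v, col, fixed = TRUE)
  )
  any_match <- Reduce(`|`, lapply(p$values, one))
  switch(op,
    eq = one(p$values[1L]),
    `in` = any_match,
    neq = !one(p$values[1L]),
    not_in = !any_match,
    stop(sprintf("operator not supported for key '%s'", p$key), call. = FALSE)
  )
}

#' Evaluate a query against a database
#'
#' Returns every statistics row satisfying all predicates (logical AND),
#' ordered by descending form frequency then form, truncated to `max_rows`.
#' Predicates on `pos` evaluate against the combined verb class `posx` (so
#' `pos = verb` matches auxiliaries) except when any value is `aux`, in which
#' case the original word class is used.
#'
#' @param db A `lexdb` with aggregates computed, or a statistics table.
#' @param query A `lexdb_query` from [parse_query()], or a query string.
#' @param max_rows Maximum number of rows to return (default 10000).
#' @return A `data.table` of result rows in canonical column order.
#' @export
#' @examples
#' db <- compute_aggregates(lexicon_from_spec(builtin_fixture("table1_silmasi")))
#' evaluate_query(db, "form = silmäsi")
evaluate_query <- function(db, query, max_rows = 10000) {
  stats <- if (inherits(db, "lexdb")) {
    if (is.null(db$stats)) stop("aggregates not computed; run compute_aggregates() first")
    db$stats
  } else {
    as.data.table(db)
  }
  if (is.character(query)) query <- parse_query(query)
  stopifnot(inherits(query, "lexdb_query"), max_rows >= 1)
  keep <- rep(TRUE, nrow(stats))
  for (p in query$predicates) keep <- keep & predicate_mask(stats, p)
  out <- stats[keep]
  setorderv(out, c("frequency", "form"), order = c(-1L, 1L))
  head(out, max_rows)
}

#' Row-by-row reference query evaluation
#'
#' Evaluates a query by direct per-row inspection with scalar comparisons and
#' no vectorized indexing. Intended as an independent correctness oracle for
#' [evaluate_query()] on small databases.
#'
#' @param db A `lexdb` with aggregates, or a statistics table.
#' @param query A `lexdb_query` or query string.
#' @return A `data.table` of matching rows (unordered, untruncated).
#' @export
brute_force_query <- function(db, query) {
  stats <- if (inherits(db, "lexdb")) db$stats else as.data.table(db)
  if (is.character(query)) query <- parse_query(query)
  match_row <- function(row, p) {
    if (p$kind == "flag") {
      val <- isTRUE(row[[p$column]])
      return(if (p$op == "flag") val else !val)
    }
    if (p$kind == "number") {
      x <- row[[p$column]]
      if (is.na(x)) return(p$op %in% c("neq", "not_in"))
      return(switch(p$op,
        eq = x == p$values[1L], neq = x != p$values[1L],
        lt = x < p$values[1L], gt = x > p$values[1L],
        `in` = x %in% p$values, not_in = !(x %in% p$values)))
    }
    x <- if (p$kind == "pos") {
      if (any(p$values == "aux")) tolower(row$pos) else tolower(row$posx)
    } else {
      tolower(row[[p$column]])
    }
    if (p$kind %in% c("pos", "feature") || p$match == "exact") {
      return(switch(p$op,
        eq = x == p$values[1L], neq = x != p$values[1L],
        `in` = x %in% p$values, not_in = !(x %in% p$values)))
    }
    hit <- function(v) switch(p$match,
      prefix = substr(x, 1L, nchar(v)) == v,
      suffix = nchar(x) >= nchar(v) &&
        substr(x, nchar(x) - nchar(v) + 1L, nchar(x)) == v,
      substring = grepl(v, x, fixed = TRUE))
    switch(p$op,
      eq = hit(p$values[1L]), neq = !hit(p$values[1L]),
      `in` = any(vapply(p$values, hit, logical(1L))),
      not_in = !any(vapply(p$values, hit, logical(1L))))
  }
  cols <- as.list(stats)
  keep <- logical(nrow(stats))
  for (i in seq_len(nrow(stats))) {
    row <- lapply(cols, `[[`, i)
    keep[i] <- all(vapply(query$predicates, function(p) match_row(row, p),
                          logical(1L)))
  }
  stats[keep]
}
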