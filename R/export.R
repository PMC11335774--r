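#' Export result rows to CSV or TSV
#'
#' Writes a header row with the canonical column names followed by the result
#' rows. CSV output follows RFC 4180 quoting; TSV output forbids literal tabs
#' or newlines inside fields (which the token charset already excludes).
#' Fractional columns (relative frequencies, average bigram frequency and the
#' ambiguity measures) are rounded to the configured precision at export;
#' stored values stay at full precision. Raw counts are written as integers.
#'
#' @param rows A statistics/result table (e.g. from [evaluate_query()]).
#' @param path Output file path.
#' @param format `"csv"` or `"tsv"`.
#' @param precision Decimal places for fractional columns (default 3).
#' @return `path`, invisibly.
#' @export
export_rows <- function(rows, path, format = c("csv", "tsv"), precision = 3L) {
  format <- match.arg(format)
  stopifnot(precision >= 0)
  out <- as.data.table(rows)
  for (col in intersect(FRACTIONAL_COLUMNS, names(out))) {
    set(out, j = col, value = round(out[[col]], precision))
  }
  for (col in intersect(c("frequency", "lemmafreq", "initrigramfreq",
                          "fintrigramfreq", "hood"), names(out))) {
    set(out, j = col, value = as.integer(round(out[[col]])))
  }
  # absent features render as empty cells, not quoted empty strings
  for (col in names(out)[vapply(out, is.character, logical(1L))]) {
    blank <- !is.na(out[[col]]) & out[[col]] == ""
    if (any(blank)) set(out, i = which(blank), j = col, value = NA_character_)
  }
  if (format == "tsv") {
    chr <- names(out)[vapply(out, is.character, logical(1L))]
    for (col in chr) {
      if (any(grepl("[\t\n\r]", out[[col]]))) {
        stop("TSV export: fields must not contain tabs or newlines")
      }
    }
    fwrite(out, path, sep = "\t", quote = FALSE, na = "")
  } else {
    fwrite(out, path, sep = ",", quote = "auto", qmethod = "double", na = "")
  }
  invisible(path)
}

#' Append a query to the history file
#'
#' Appends a timestamped line with the query text, result count and elapsed
#' time. Logging failures never abort the query; with an empty path the call
#' is a no-op (history disabled).
#'
#' @param history_file Path of the history file, or `""` to disable.
#' @param query_text The query as typed.
#' @param row_count Number of result rows.
#' @param elapsed Elapsed seconds.
#' @return `TRUE` if a line was written, else `FALSE` (invisibly).
#' @export
log_query <- function(history_file, query_text, row_count, elapsed = NA_real_) {
  if (is.null(history_file) || !nzchar(history_file)) return(invisible(FALSE))
  line <- sprintf("%s\t%s\t%d\t%.3f",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  query_text, as.integer(row_count), elapsed)
  ok <- tryCatch({
    con <- file(history_file, open = "at")
    on.exit(close(con))
    writeLines(line, con, useBytes = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  invisible(ok)
}
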