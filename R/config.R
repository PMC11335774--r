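#' Read an INI configuration file
#'
#' Minimal INI reader: `[section]` headers, `key = value` pairs, `;` or `#`
#' comment lines. Values are returned as strings; keys are lowercased.
#'
#' @param path File path or character vector of lines.
#' @return Named list of sections, each a named list of values.
#' @export
read_ini <- function(path) {
  lines <- if (length(path) == 1L && !grepl("\n", path) && file.exists(path)) {
    readLines(path, encoding = "UTF-8", warn = FALSE)
  } else {
    unlist(strsplit(path, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, ";") & !startsWith(lines, "#")]
  out <- list()
  section <- "default"
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- tolower(substr(ln, 2L, nchar(ln) - 1L))
      next
    }
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0L) stop(sprintf("malformed INI line: '%s'", ln))
    key <- tolower(trimws(substr(ln, 1L, eq - 1L)))
    val <- trimws(substr(ln, eq + 1L, nchar(ln)))
    out[[section]][[key]] <- val
  }
  out
}

#' Application configuration
#'
#' Builds the effective configuration from built-in defaults, an optional INI
#' file (section `[lexdb]`), and explicit overrides, in increasing order of
#' precedence (command-line flags are passed as overrides and win).
#'
#' @param ini Optional path to an INI file.
#' @param overrides Named list of settings overriding the INI values.
#' @return A named list: `max_rows` (default 10000), `precision` (export
#'   decimals, default 3), `minfreq` (prune threshold, default 0), `language`,
#'   `charset`, `autofreq` / `hood_minfreq` (neighborhood), `history_file`
#'   (`""` disables query logging), `database`.
#' @export
app_config <- function(ini = NULL, overrides = list()) {
  cfg <- list(
    max_rows = 10000L, precision = 3L, minfreq = 0, language = "fi",
    charset = FI_CHARSET, autofreq = 10000, hood_minfreq = 100,
    history_file = "", database = ""
  )
  numeric_keys <- c("max_rows", "precision", "minfreq", "autofreq",
                    "hood_minfreq")
  apply_layer <- function(cfg, layer) {
    for (k in names(layer)) {
      if (is.null(layer[[k]])) next
      if (!k %in% names(cfg)) stop(sprintf("unknown configuration key '%s'", k))
      v <- layer[[k]]
      if (k %in% numeric_keys) v <- as.numeric(v)
      cfg[[k]] <- v
    }
    cfg
  }
  if (!is.null(ini)) {
    parsed <- read_ini(ini)
    cfg <- apply_layer(cfg, parsed[["lexdb"]])
  }
  cfg <- apply_layer(cfg, overrides)
  stopifnot(cfg$max_rows >= 1, cfg$precision >= 0)
  cfg
}
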