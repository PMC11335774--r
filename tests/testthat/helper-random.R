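# Randomized fixtures for property-style tests. Everything is driven by an
# explicit seed so failures are reproducible.

FI_POOL_LETTERS <- c("a", "e", "i", "k", "l", "m", "n", "o", "s", "t", "u", "ä")

random_word <- function(min_len = 2L, max_len = 8L) {
  n <- sample(min_len:max_len, 1L)
  paste(sample(FI_POOL_LETTERS, n, replace = TRUE), collapse = "")
}

# A random corpus specification: a pool of forms, some shared between several
# lemma/word-class readings (so ambiguity measures are exercised), with random
# core features and multiplicities.
random_spec <- function(n_forms = 40L, max_mult = 500L, share_prob = 0.3) {
  forms <- unique(replicate(n_forms, random_word()))
  pos_pool <- c("NOUN", "VERB", "AUX", "ADJ", "ADV", "PROPN", "INTJ")
  case_pool <- c("Nom", "Gen", "Ine", "Ela", "Par", "")
  num_pool <- c("Sing", "Plur", "")
  rows <- lapply(forms, function(f) {
    n_read <- 1L + stats::rbinom(1L, 2L, share_prob)
    data.table::data.table(
      lemma = vapply(seq_len(n_read), function(i) random_word(2L, 6L), ""),
      upos = sample(pos_pool, n_read, replace = TRUE),
      form = f,
      feats = vapply(seq_len(n_read), function(i) {
        cs <- sample(case_pool, 1L); nm <- sample(num_pool, 1L)
        parts <- c(if (nzchar(cs)) paste0("Case=", cs),
                   if (nzchar(nm)) paste0("Number=", nm))
        if (length(parts)) paste(parts, collapse = "|") else "_"
      }, ""),
      multiplicity = sample(max_mult, n_read, replace = TRUE)
    )
  })
  rows <- data.table::rbindlist(rows)
  rows <- unique(rows, by = c("lemma", "upos", "form", "feats"))
  corpus_spec(rows, seed = sample(1e6, 1L))
}

random_lexicon <- function(n_forms = 40L, ...) {
  lexicon_from_spec(random_spec(n_forms = n_forms, ...))
}

random_aggregated <- function(n_forms = 40L, ...) {
  compute_aggregates(random_lexicon(n_forms = n_forms, ...),
                     hood_params = neighborhood_params(autofreq = 300,
                                                       minfreq = 10))
}

# A random query string with 1-3 predicates, random casing and spacing, built
# only from constructs the grammar documents.
random_query_text <- function(stats) {
  n_pred <- sample(3L, 1L)
  one <- function() {
    kind <- sample(c("num", "feat", "text", "flag", "pos"), 1L,
                   prob = c(0.35, 0.25, 0.2, 0.1, 0.1))
    sp <- function() sample(c("", " ", "  "), 1L)
    if (kind == "num") {
      key <- sample(c("len", "frequency", "ambform", "hood", "relfrequency"), 1L)
      op <- sample(c("=", "!=", "<", ">"), 1L)
      val <- if (key == "ambform") round(stats::runif(1L), 2L) else
        sample(c(1L, 2L, 3L, 5L, 50L, 500L), 1L)
      paste0(key, sp(), op, sp(), val)
    } else if (kind == "feat") {
      key <- sample(c("case", "number"), 1L)
      vals <- if (key == "case") c("nom", "gen", "ine", "ela", "par") else
        c("sing", "plur")
      op <- sample(c("=", "!=", "in", "not in"), 1L)
      if (op %in% c("in", "not in")) {
        k <- min(length(vals), sample(2L, 1L) + 1L)
        paste(key, op, paste(sample(vals, k), collapse = ","))
      } else {
        paste0(key, sp(), op, sp(), sample(vals, 1L))
      }
    } else if (kind == "text") {
      key <- sample(c("start", "end", "mid", "form", "lemma"), 1L)
      src <- if (key == "lemma") stats$lemma else stats$form
      w <- sample(src, 1L)
      frag <- if (key == "start") substr(w, 1L, 2L) else
        if (key == "end") substr(w, nchar(w) - 1L, nchar(w)) else
        if (key == "mid") substr(w, 2L, 3L) else w
      op <- sample(c("=", "in"), 1L)
      if (op == "in") paste(key, "in", paste(c(frag, "zz"), collapse = ",")) else
        paste0(key, sp(), "=", sp(), frag)
    } else if (kind == "flag") {
      sample(c("proper", "not proper", "compound", "not compound"), 1L)
    } else {
      op <- sample(c("=", "!=", "in"), 1L)
      vals <- sample(c("noun", "verb", "aux", "adj"), if (op == "in") 2L else 1L)
      paste(sample(c("pos", "POS", "Pos"), 1L), op, paste(vals, collapse = ","))
    }
  }
  paste(replicate(n_pred, one()), collapse = " and ")
}

# Exhaustive O(n^2) neighborhood reference: pairwise Hamming check plus the
# frequency/oracle filter rules.
oracle_hood <- function(forms, freqs, autofreq, minfreq, oracle = NULL) {
  hamming1 <- function(a, b) {
    if (nchar(a) != nchar(b)) return(FALSE)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]) == 1L
  }
  included <- freqs >= autofreq |
    (freqs >= minfreq & (if (is.null(oracle)) TRUE else oracle(forms)))
  vapply(seq_along(forms), function(i) {
    sum(vapply(which(included), function(j) {
      j != i && hamming1(forms[i], forms[j])
    }, logical(1)))
  }, integer(1))
}

# One NOUN entry per form with the given frequency.
spec_db2 <- function(forms, freqs) {
  rows <- data.table::data.table(lemma = forms, upos = "NOUN", form = forms,
                                 feats = "_", multiplicity = freqs)
  lexicon_from_spec(corpus_spec(rows))
}

# Sort result rows canonically so result sets can be compared as sets.
sort_rows <- function(x) {
  x <- data.table::copy(data.table::as.data.table(x))
  data.table::setkey(x, NULL)
  data.table::setorderv(x, c("lemma", "pos", "form", "feats"))
  x
}
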