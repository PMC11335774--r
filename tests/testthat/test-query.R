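test_that("tokenizer lowercases and splits on the standalone word 'and'", {
  expect_equal(tokenize_query("lemma = voi and pos = noun"),
               c("lemma = voi", "pos = noun"))
  expect_equal(tokenize_query("len> 5 and len< 9"), c("len> 5", "len< 9"))
  expect_equal(tokenize_query("Case = Ine"), "case = ine")
  # 'and' inside a word does not split
  expect_equal(tokenize_query("lemma = kanta"), "lemma = kanta")
  expect_error(tokenize_query(""), "empty query")
  expect_error(tokenize_query("len > 5 and"), "empty query part")
})

test_that("parser compiles all documented constructs", {
  q <- parse_query("case in ine,gen")
  expect_equal(q$predicates[[1]][c("key", "op")], list(key = "case", op = "in"))
  expect_equal(q$predicates[[1]]$values, c("ine", "gen"))

  q <- parse_query("not compound")
  expect_equal(q$predicates[[1]]$op, "not_flag")
  q <- parse_query("proper")
  expect_equal(q$predicates[[1]]$op, "flag")

  q <- parse_query("derivation != ja")
  expect_equal(q$predicates[[1]][c("key", "op")],
               list(key = "derivation", op = "neq"))

  q <- parse_query("posspers not in 1, 2, 3")
  expect_equal(q$predicates[[1]]$values, c("1", "2", "3"))

  q <- parse_query("ambform< 0.95")
  expect_equal(q$predicates[[1]]$op, "lt")
  expect_equal(q$predicates[[1]]$values, 0.95)
})

test_that("parser rejects what the grammar excludes", {
  expect_error(parse_query("foo = 1"), "unknown query key 'foo'")
  expect_error(parse_query("len < 10 or len > 20"), "unsupported operator OR")
  expect_error(parse_query("lemma < voi"), "requires a numeric key")
  expect_error(parse_query("len = paljon"), "non-numeric")
  expect_error(parse_query("compound = 1"), "takes no value")
  expect_error(parse_query("form ="), "malformed|missing")
  expect_error(parse_query("case in "), "malformed")
})

test_that("the Condition-A style compound query parses as a whole", {
  q <- parse_query(paste(
    "pos in NOUN,NUM and end in sta,na,a and case = Nom and number = Sing",
    "and len> 5 and len< 9 and rellemmafreq> 1 and relfrequency> 0.1",
    "and not compound and posspers not in 1, 2, 3 and clitic not in Kin, Han",
    "and derivation != Ja and ambform< 0.95"
  ))
  expect_length(q$predicates, 13L)
})

test_that("text keys match exactly; start/end/mid match by position", {
  db <- spec_db2(c("kiista", "kana", "auto"), c(10, 20, 30))
  db <- compute_aggregates(db)
  expect_equal(evaluate_query(db, "end in sta,na")$form, c("kana", "kiista"))
  expect_equal(evaluate_query(db, "start = ka")$form, "kana")
  expect_equal(evaluate_query(db, "mid = ist")$form, "kiista")
  expect_equal(evaluate_query(db, "form = auto")$form, "auto")
  expect_equal(nrow(evaluate_query(db, "form = kis")), 0L)
})

test_that("pos queries use the combined verb class except for aux", {
  rows <- data.table::data.table(
    lemma = c("olla", "voida", "talo"),
    upos = c("AUX", "VERB", "NOUN"),
    form = c("olla", "voida", "talo"),
    feats = "_", multiplicity = c(10, 20, 30)
  )
  db <- compute_aggregates(lexicon_from_spec(corpus_spec(rows)))
  verb <- evaluate_query(db, "pos = verb")
  aux <- evaluate_query(db, "pos = aux")
  expect_equal(sort(verb$form), c("olla", "voida"))
  expect_equal(aux$form, "olla")
  # aux results are a subset of verb results
  expect_true(all(aux$form %in% verb$form))
  expect_equal(evaluate_query(db, "pos != aux")$form, c("talo", "voida"))
  expect_equal(sort(evaluate_query(db, "pos in aux,noun")$form),
               c("olla", "talo"))
})

test_that("rows lacking a feature fail positive and pass negative predicates", {
  rows <- data.table::data.table(
    lemma = c("käsi", "talo"), upos = "NOUN",
    form = c("käteni", "talo"),
    feats = c("Case=Nom|Number=Sing|Person[psor]=1", "Case=Nom|Number=Sing"),
    multiplicity = c(5, 10)
  )
  db <- compute_aggregates(lexicon_from_spec(corpus_spec(rows)))
  expect_equal(evaluate_query(db, "posspers = 1")$form, "käteni")
  expect_equal(evaluate_query(db, "posspers not in 1,2,3")$form, "talo")
  expect_equal(evaluate_query(db, "posspers != 1")$form, "talo")
  # undefined numeric trigram features behave the same way: both forms start
  # with "abc" so the table count is 10, and the length-3 form has no feature
  db2 <- compute_aggregates(spec_db2(c("abc", "abcd"), c(5, 5)))
  expect_equal(evaluate_query(db2, "initrigramfreq > 0")$form, "abcd")
  expect_equal(sort(evaluate_query(db2, "initrigramfreq != 10")$form), "abc")
})

test_that("queries are case-insensitive end to end", {
  db <- random_aggregated(n_forms = 25L)
  q1 <- evaluate_query(db, "case = nom and len > 3")
  q2 <- evaluate_query(db, "CASE = Nom AND LEN > 3")
  expect_equal(q1, q2)
})

test_that("results order by descending frequency and truncate at max_rows", {
  db <- compute_aggregates(spec_db2(c("aaa", "bbb", "ccc"), c(5, 50, 20)))
  out <- evaluate_query(db, "len = 3")
  expect_equal(out$form, c("bbb", "ccc", "aaa"))
  expect_equal(nrow(evaluate_query(db, "len = 3", max_rows = 2)), 2L)
})

test_that("conjunction is order-independent and never enlarges results", {
  db <- random_aggregated(n_forms = 40L)
  a <- evaluate_query(db, "len > 3 and case = nom")
  b <- evaluate_query(db, "case = nom and len > 3")
  expect_equal(sort_rows(a), sort_rows(b))
  base <- evaluate_query(db, "len > 3")
  expect_lte(nrow(a), nrow(base))
})

test_that("'in' and 'not in' partition the rows for fully defined keys", {
  db <- random_aggregated(n_forms = 40L)
  yes <- evaluate_query(db, "pos in noun,adj")
  no <- evaluate_query(db, "pos not in noun,adj")
  expect_equal(nrow(yes) + nrow(no), nrow(db$stats))
  expect_length(intersect(
    do.call(paste, sort_rows(yes)[, .(lemma, pos, form, feats)]),
    do.call(paste, sort_rows(no)[, .(lemma, pos, form, feats)])
  ), 0L)
})

test_that("evaluate matches the row-by-row reference on random queries", {
  set.seed(23)
  n_total <- 0L
  for (d in 1:6) {
    db <- random_aggregated(n_forms = 35L, share_prob = 0.5)
    for (k in 1:25) {
      qtext <- random_query_text(db$stats)
      got <- evaluate_query(db, qtext, max_rows = nrow(db$stats))
      want <- brute_force_query(db, qtext)
      expect_equal(sort_rows(got), sort_rows(want), info = qtext)
      n_total <- n_total + 1L
    }
  }
  expect_gte(n_total, 150L)
})

test_that("empty predicate handling: contradictions give empty results", {
  db <- random_aggregated(n_forms = 20L)
  expect_equal(nrow(evaluate_query(db, "len > 9 and len < 5")), 0L)
})
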