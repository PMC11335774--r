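test_that("read_conllu maps syntactic-word rows and lowercases", {
  txt <- c(
    "# newdoc",
    "# sent_id = 1",
    "1\tAutossa\tauto\tNOUN\t_\tCase=Ine|Number=Sing\t0\troot\t_\t_",
    "2-3\tettei\t_\t_\t_\t_\t_\t_\t_\t_",
    "2\tettä\tettä\tSCONJ\t_\t_\t3\tmark\t_\t_",
    "3\tei\tei\tAUX\t_\tPolarity=Neg\t1\taux\t_\t_",
    "3.1\tellipsis\t_\t_\t_\t_\t_\t_\t_\t_",
    ""
  )
  tok <- read_conllu(txt)
  expect_equal(nrow(tok), 3L)  # range row and empty node skipped
  expect_equal(tok$form, c("autossa", "että", "ei"))
  expect_equal(tok$lemma[1], "auto")
  expect_equal(tok$upos, c("NOUN", "SCONJ", "AUX"))
  expect_equal(tok$feats[2], "_")
})

test_that("read_conllu handles empty input and reports malformed rows", {
  expect_equal(nrow(read_conllu(character())), 0L)
  expect_equal(nrow(read_conllu("# only a comment")), 0L)
  bad <- c("# c", "1\tauto\tauto\tNOUN\t_\t_\t0\troot\t_\t_",
           "2\tbroken\trow")
  expect_error(read_conllu(bad), "line 3.*10 tab-separated")
})

test_that("accept_token enforces charset, first character, letter and length", {
  expect_true(accept_token("auto"))
  expect_false(accept_token("2017"))       # no letter
  expect_false(accept_token("a"))          # too short
  expect_true(accept_token("a2"))          # letter plus digit is fine
  expect_false(accept_token(strrep("a", 101L)))  # too long
  expect_true(accept_token(strrep("a", 100L)))
  expect_false(accept_token("-auto"))      # must start alphanumeric
  expect_true(accept_token("linja-auto"))  # internal hyphen allowed
  expect_false(accept_token("aut!o"))      # charset violation
  expect_false(accept_token("über"))       # foreign letter
  expect_true(accept_token("šakki"))
  # both form and lemma must pass
  expect_false(accept_token("auto", lemma = "a"))
  expect_true(accept_token("auto", lemma = "auto"))
  # pure predicate: lowercasing before acceptance is idempotent
  words <- c("Auto", "auto", "2017", "a", "kärpänen")
  expect_equal(accept_token(tolower(words)), accept_token(tolower(tolower(words))))
})

test_that("project_core_features keeps the eleven core keys canonically", {
  fc <- project_core_features("Case=Nom|Number=Plur")
  expect_equal(fc$feats, "Case=Nom|Number=Plur")
  expect_equal(fc$case, "Nom")
  expect_equal(fc$number, "Plur")
  # dropped features disappear; remaining serialization is canonical
  fc <- project_core_features("Degree=Pos|Case=Nom")
  expect_equal(fc$feats, "Case=Nom")
  # canonical order is fixed regardless of input order
  a <- project_core_features("Number=Plur|Case=Nom")
  b <- project_core_features("Case=Nom|Number=Plur")
  expect_equal(a$feats, b$feats)
  # possessor features
  fc <- project_core_features("Case=Nom|Number=Sing|Number[psor]=Sing|Person[psor]=2")
  expect_equal(fc$posspers, "2")
  expect_equal(fc$possnum, "Sing")
  expect_equal(fc$feats, "Case=Nom|Number=Sing|Person[psor]=2|Number[psor]=Sing")
  # empty set serializes as the sentinel
  expect_equal(project_core_features("_")$feats, "_")
  expect_equal(project_core_features("")$feats, "_")
  expect_equal(project_core_features("Degree=Pos")$feats, "_")
})

test_that("build_lexicon aggregates by the full quadruple", {
  tok <- data.table::data.table(
    form = c("silmäsi", "silmäsi", "silmäsi"),
    lemma = "silmä", upos = "NOUN",
    feats = "Case=Nom|Number=Sing"
  )
  db <- build_lexicon(tok)
  expect_equal(nrow(db$entries), 1L)
  expect_equal(db$entries$frequency, 3)
  expect_equal(db$total_tokens, 3)
  expect_equal(db$entries$len, 7L)
})

test_that("tokens differing only in a dropped feature merge into one entry", {
  tok <- data.table::data.table(
    form = "suuri", lemma = "suuri", upos = "ADJ",
    feats = c("Case=Nom|Degree=Pos", "Case=Nom|Degree=Cmp", "Case=Nom")
  )
  db <- build_lexicon(tok)
  expect_equal(nrow(db$entries), 1L)
  expect_equal(db$entries$frequency, 3)
  expect_equal(db$entries$feats, "Case=Nom")
})

test_that("compounds are flagged and the separator stripped; proper nouns flagged", {
  tok <- data.table::data.table(
    form = c("linja-auto", "Matti"),
    lemma = c("linja#auto", "Matti"),
    upos = c("NOUN", "PROPN"),
    feats = "_"
  )
  db <- build_lexicon(tok)
  ent <- db$entries[order(form)]
  expect_setequal(ent$lemma, c("linjaauto", "matti"))  # separator stripped
  expect_true(ent[form == "linja-auto"]$compound)
  expect_false(ent[form == "matti"]$compound)
  expect_true(ent[form == "matti"]$proper)
  expect_equal(ent[form == "linja-auto"]$lemma, "linjaauto")
})

test_that("rejected tokens contribute nothing to the database", {
  tok <- data.table::data.table(
    form = c("auto", "2017", "a", "auto"),
    lemma = c("auto", "2017", "a", "auto"),
    upos = "NOUN", feats = "_"
  )
  db <- build_lexicon(tok)
  expect_equal(db$total_tokens, 2)
  expect_equal(nrow(db$entries), 1L)
})

test_that("posx combines auxiliary and main verbs only", {
  expect_equal(compute_posx(c("AUX", "VERB", "NOUN", "PROPN")),
               c("VERB", "VERB", "NOUN", "PROPN"))
})
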