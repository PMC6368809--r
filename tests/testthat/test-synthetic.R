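test_that("corpus generation is fully determined by the seed", {
  st <- demo_study(seed = 5, n_documents = 40)
  g1 <- generate_corpus(st$spec)
  g2 <- generate_corpus(st$spec)
  expect_identical(g1$corpus$text, g2$corpus$text)
  expect_identical(g1$truth, g2$truth)

  st2 <- demo_study(seed = 6, n_documents = 40)
  expect_false(identical(generate_corpus(st2$spec)$corpus$text, g1$corpus$text))
})

test_that("planted co-occurrence rates concentrate around their target", {
  lex <- as_lexicon(tibble::tibble(
    entry_id = c("TA", "TB", "TC"),
    pattern = c("alpha", "beta", "gamma"),
    payload_kind = "category",
    payload_value = c("GO:1", "GO:2", "GO:3")
  ))
  spec <- corpus_spec(
    n_documents = 2000L, sentences_per_document = c(1L, 1L), lexicon = lex,
    planted_pairs = tibble::tibble(a = c("TA", "TA"), b = c("TB", "TC"),
                                   rate = c(0.3, 0), connector = "pronoun"),
    seed = 19L)
  g <- generate_corpus(spec)
  sents <- protlogic:::corpus_sentences(g$corpus)
  expect_equal(nrow(sents), 2000L)
  both <- function(x, y) {
    mean(vapply(sents$tokens, function(tk) x %in% tk && y %in% tk, logical(1)))
  }
  expect_lt(abs(both("alpha", "beta") - 0.3), 0.03)
  expect_equal(both("alpha", "gamma"), 0)
})

test_that("planted connector types drive the extracted relatedness labels", {
  lex <- tiny_lexicon()
  planted <- tibble::tibble(
    a = c("PU1", "PU1"), b = c("FOLD", "STRUCT"), rate = c(0.5, 0.5),
    connector = c("pronoun", "disconnector"), anchor = c("PA", "PA"))
  spec <- corpus_spec(n_documents = 120L, sentences_per_document = c(1L, 2L),
                      lexicon = lex, planted_pairs = planted, seed = 23L)
  g <- generate_corpus(spec)
  idx <- build_related_pair_index(g$corpus, lex)
  expect_true(has_pair(idx, "PU1", "FOLD"))
  expect_false(has_pair(idx, "PU1", "STRUCT"))
  expect_equal(g$truth$atoms$atom, "FD(PA)")
})

test_that("the worked-example fixtures encode the published line counts", {
  fx <- worked_example_fixtures()
  expect_named(fx, c("ex1", "ex2", "ex3", "ex4"))
  expect_equal(vapply(fx, function(e) nrow(e$proof), integer(1)),
               c(ex1 = 5L, ex2 = 13L, ex3 = 5L, ex4 = 9L))
  expect_equal(fx$ex1$given_text, c("FD(Px)", "ST(Px)"))
  expect_equal(fx$ex4$given_text, c("NCBND(Px, Py)", "F(Px)"))
  for (e in fx) {
    expect_true(check_proof(e$proof, e$given, table1_rules)$valid)
    expect_true(e$proof$text[[nrow(e$proof)]] %in% e$conclusions)
  }
})
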