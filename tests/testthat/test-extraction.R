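test_that("sentence segmentation splits on terminators but not abbreviations", {
  s <- segment_sentences("A binds B. C folds.", "d1")
  expect_equal(nrow(s), 2L)
  expect_equal(s$sentence_index, c(0L, 1L))
  expect_equal(s$tokens[[1]], c("a", "binds", "b"))

  s2 <- segment_sentences("Chaperones, e.g. Hsp70, assist folding. They bind.")
  expect_equal(nrow(s2), 2L)
  expect_match(s2$text[[1]], "e\\.g\\.")

  expect_equal(nrow(segment_sentences("a single sentence without a period")), 1L)
  expect_equal(nrow(segment_sentences("   ")), 0L)
})

test_that("dictionary matching is longest-first, non-overlapping, case-insensitive", {
  lex <- tiny_lexicon()
  s <- segment_sentences("The Amino Acid Sequence of PA was compared to a short sequence.", "d1")
  m <- match_terms(s[1, ], lex)
  aasq <- m[m$entry_id == "AASQ", ]
  expect_equal(nrow(aasq), 2L)
  # the three-token pattern wins at the front; the bare "sequence" matches later
  expect_equal(aasq$end[1] - aasq$start[1], 3L)
  expect_equal(aasq$surface, c("amino acid sequence", "sequence"))

  # template payloads bind to the nearest protein name
  expect_equal(aasq$atom[[1]], "AAS(PA)")

  none <- match_terms(segment_sentences("nothing relevant here.")[1, ], lex)
  expect_equal(nrow(none), 0L)
})

test_that("template binding picks the nearest name, ties to the left", {
  lex <- tiny_lexicon()
  s <- segment_sentences("PA interacts while PU1 controls folding strongly.", "d1")
  m <- match_terms(s[1, ], lex)
  # PU1 (distance 1) is nearer to "folding" than PA (distance 4)
  expect_equal(m$atom[m$entry_id == "FOLD"], "FD(PU1)")

  s2 <- segment_sentences("PA folding PU1.", "d1")
  m2 <- match_terms(s2[1, ], lex)
  # equidistant: the leftward mention wins
  expect_equal(m2$atom[m2$entry_id == "FOLD"], "FD(PA)")
})

test_that("pair classification follows the pronoun and disconnector rules", {
  lex <- tiny_lexicon()
  s <- segment_sentences("PU1 , which regulates apoptosis strongly.", "d1")
  m <- match_terms(s[1, ], lex)
  a <- m[m$entry_id == "PU1", ]; b <- m[m$entry_id == "APO", ]
  expect_equal(classify_pair(s[1, ], a, b)$label, "related")
  # symmetric in the two mentions
  expect_equal(classify_pair(s[1, ], b, a)$label, "related")

  s2 <- segment_sentences("PU1 was stable whereas folding failed.", "d1")
  m2 <- match_terms(s2[1, ], lex)
  cls2 <- classify_pair(s2[1, ], m2[m2$entry_id == "PU1", ],
                        m2[m2$entry_id == "FOLD", ])
  expect_equal(cls2$label, "unrelated")
  expect_equal(cls2$connector, "whereas")

  # a disconnector beats a pronoun anywhere in between
  s2b <- segment_sentences("PU1 , which was stable while folding failed.", "d1")
  m2b <- match_terms(s2b[1, ], lex)
  expect_equal(classify_pair(s2b[1, ], m2b[m2b$entry_id == "PU1", ],
                             m2b[m2b$entry_id == "FOLD", ])$label, "unrelated")

  s3 <- segment_sentences("PU1 and folding were measured.", "d1")
  m3 <- match_terms(s3[1, ], lex)
  expect_equal(classify_pair(s3[1, ], m3[m3$entry_id == "PU1", ],
                             m3[m3$entry_id == "FOLD", ])$label, "undetermined")

  expect_error(classify_pair(s3[1, ], m3[m3$entry_id == "PU1", ],
                             m3[m3$entry_id == "PU1", ]), class = "pl_overlap")
})

test_that("the collocation Z-score matches its closed form", {
  # k exactly at the independence expectation: z = 0
  expect_equal(compute_zscore(10, 100, 100, 1000), 0)

  # frozen values from independent evaluation of the closed form
  expect_equal(compute_zscore(40, 50, 50, 1000), 37.5 / sqrt(2.5 * 0.9975))
  expect_equal(compute_zscore(40, 50, 50, 1000), 23.7468, tolerance = 1e-4)
  expect_equal(compute_zscore(0, 1, 1, 1000), -0.0316, tolerance = 1e-3)

  expect_error(compute_zscore(0, 0, 1, 10), class = "pl_degenerate_p")
  expect_error(compute_zscore(5, 5, 5, 5), class = "pl_degenerate_p")
  expect_error(compute_zscore(6, 5, 8, 10), class = "pl_bad_arg")
  expect_error(compute_zscore(1, 5, 8, 0), class = "pl_bad_arg")
})

test_that("the related-pair index requires pronoun evidence and significance", {
  lex <- tiny_lexicon()
  texts <- c(
    rep("PU1 , which regulates apoptosis. Unrelated filler text here.", 6),
    rep("PU1 was measured whereas folding failed. More filler text.", 6),
    rep("Background sentence about structure alone.", 8)
  )
  idx <- build_related_pair_index(tiny_corpus(texts), lex)
  expect_true(has_pair(idx, "PU1", "APO"))
  expect_true(has_pair(idx, "APO", "PU1"))  # order-free storage
  # co-occurs often, but only ever across a disconnector
  expect_false(has_pair(idx, "PU1", "FOLD"))
  expect_false(has_pair(idx, "PU1", "STRUCT"))

  empty <- build_related_pair_index(tiny_corpus(character(0)), lex)
  expect_equal(nrow(empty), 0L)
})

test_that("given-premise extraction yields atoms and categories with provenance", {
  lex <- tiny_lexicon()
  texts <- c(
    "PU1 , which involves the folding of PA. Filler sentence one.",
    "PU1 , which involves the structure of PA. Filler sentence two.",
    "PU1 , which regulates apoptosis. Filler sentence three."
  )
  corpus <- tiny_corpus(texts)
  prem <- extract_given_premises(corpus, "PU1", lex)
  expect_setequal(unique(prem$atoms$atom), c("FD(PA)", "ST(PA)"))
  expect_equal(unique(prem$categories$category), "GO:0042981")
  expect_true(all(prem$atoms$doc_id %in% corpus$doc_id))

  # invariant to document order
  prem_rev <- extract_given_premises(corpus[nrow(corpus):1, ], "PU1", lex)
  expect_equal(prem_rev$atoms$atom, prem$atoms$atom)
  expect_equal(prem_rev$categories, prem$categories)

  # every constant in an emitted atom is mentioned in the cited sentence
  for (i in seq_len(nrow(prem$atoms))) {
    sent <- segment_sentences(corpus$text[[match(prem$atoms$doc_id[[i]],
                                                 corpus$doc_id)]],
                              prem$atoms$doc_id[[i]])
    toks <- sent$tokens[[prem$atoms$sentence_index[[i]] + 1L]]
    consts <- protlogic:::formula_constants(list(prem$atoms$formula[[i]]))
    for (cn in consts) expect_true(tolower(cn$name) %in% toks)
  }

  # disconnector-only corpora yield nothing
  dis <- tiny_corpus(rep("PU1 was measured whereas folding failed. Filler.", 4))
  prem2 <- extract_given_premises(dis, "PU1", lex)
  expect_equal(nrow(prem2$atoms), 0L)
  expect_equal(nrow(prem2$categories), 0L)

  expect_error(extract_given_premises(corpus, "NOPE", lex),
               class = "pl_unknown_protein")
  expect_error(extract_given_premises(tiny_corpus("text.", protein = "PA"),
                                      "PU1", lex),
               class = "pl_protein_not_in_corpus")
})

test_that("a training index gates query-corpus extraction", {
  lex <- tiny_lexicon()
  train <- tiny_corpus(c(
    rep("PU1 , which involves the folding of PA. Filler.", 5),
    rep("Background filler sentence.", 5)
  ))
  idx <- build_related_pair_index(train, lex)
  query <- tiny_corpus(c(
    "PU1 , which involves the folding of PA. Filler.",
    "PU1 , which regulates apoptosis. Filler."
  ))
  # apoptosis pair is related in the query but absent from the training index
  prem <- extract_given_premises(query, "PU1", lex, index = idx)
  expect_equal(unique(prem$atoms$atom), "FD(PA)")
  expect_equal(nrow(prem$categories), 0L)
})
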