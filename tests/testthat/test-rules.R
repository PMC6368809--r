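test_that("the bundled rule file yields the thirteen premises verbatim", {
  expect_equal(nrow(table1_rules), 13L)
  expect_equal(table1_rules$id, paste0("R", 1:13))

  canonical <- c(
    R1  = "FD(Px) -> (ST(Px) -> F(Px))",
    R2  = "AAS(Px) -> ST(Px)",
    R3  = "AAS(Px) -> F(Px)",
    R4  = "CBND(Px, Ly) | AAS(Px) -> ST(Px)",
    R5  = "FD(Px) | ST(Px) -> F(Px)",
    R6  = "PPI(Px, Py) -> PCF(Px, Py)",
    R7  = "PCF(Px, Py) -> (F(Px) -> F(Py))",
    R8  = "PCF(Px, Py) -> (F(Px) | F(Py))",
    R9  = "ST(Px) & ST(Py) -> (F(Px) -> F(Py))",
    R10 = "AAS(Px) & AAS(Py) -> (ST(Px) -> F(Py))",
    R11 = "CBND(Px, Ly) & F(Px) -> AAS(Px)",
    R12 = "NCBND(Px, Py) -> PPI(Px, Py)",
    R13 = "ST(Px) -> AAS(Px)"
  )
  expect_equal(stats::setNames(table1_rules$text, table1_rules$id), canonical)

  # the fully parenthesised spellings (as conventionally printed) parse to
  # structurally identical formulas
  printed <- c(
    R4 = "(CBND(Px, Ly) | AAS(Px)) -> ST(Px)",
    R5 = "(FD(Px) | ST(Px)) -> F(Px)",
    R9 = "(ST(Px) & ST(Py)) -> (F(Px) -> F(Py))",
    R10 = "(AAS(Px) & AAS(Py)) -> (ST(Px) -> F(Py))"
  )
  for (id in names(printed)) {
    expect_identical(
      protlogic:::fkey(parse_formula(printed[[id]], variables = "all")),
      protlogic:::fkey(table1_rules$formula[[match(id, table1_rules$id)]]),
      info = id)
  }
})

test_that("rule-file parsing enforces its format", {
  expect_equal(nrow(parse_rule_file(text = "")), 0L)
  expect_equal(nrow(parse_rule_file(text = "# only a comment\n\n")), 0L)

  expect_error(parse_rule_file(text = "R1: ST(Px)\nR1: FD(Px)"),
               class = "pl_duplicate_id")
  err <- tryCatch(parse_rule_file(text = "R1: ST(Px)\nR2: ST(Px"),
                  error = function(e) e)
  expect_match(conditionMessage(err), "line 2")

  one <- parse_rule_file(text = "Rx: FD(Px) -> F(Px)  # trailing comment")
  expect_equal(one$id, "Rx")
  expect_true(one$formula[[1]]$lhs$args[[1]]$var)
})
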