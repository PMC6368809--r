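test_that("the DSL parses rule formulas with the documented precedence", {
  f <- parse_formula("FD(Px) -> (ST(Px) -> F(Px))")
  expect_equal(f$type, "implies")
  expect_equal(f$lhs$type, "atom")
  expect_equal(f$lhs$pred, "FD")
  expect_equal(f$rhs$type, "implies")
  expect_equal(serialize_formula(f), "FD(Px) -> (ST(Px) -> F(Px))")

  # implication is right-associative: a -> b -> c == a -> (b -> c)
  g <- parse_formula("FD(A) -> ST(A) -> F(A)")
  expect_equal(protlogic:::fkey(g), protlogic:::fkey(
    parse_formula("FD(A) -> (ST(A) -> F(A))")))

  # & binds tighter than ->, | tighter than ->
  h <- parse_formula("CBND(Px, Ly) & F(Px) -> AAS(Px)", variables = "all")
  expect_equal(h$type, "implies")
  expect_equal(h$lhs$type, "and")
  expect_equal(h$lhs$lhs$pred, "CBND")
  expect_true(h$lhs$lhs$args[[2]]$var)
  expect_equal(h$lhs$lhs$args[[2]]$sort, "ligand")

  a <- parse_formula("ST(Px)")
  expect_equal(a$type, "atom")
  expect_false(a$args[[1]]$var)
})

test_that("parser rejects malformed input with informative conditions", {
  expect_error(parse_formula("FD(Px) -> "), class = "pl_syntax_error")
  expect_error(parse_formula("FOO(Px)"), class = "pl_unknown_predicate")
  expect_error(parse_formula("FD(Px, Py)"), class = "pl_bad_arity")
  expect_error(parse_formula("CBND(Px)"), class = "pl_bad_arity")
  # B is forced to sort ligand by CBND then used as a protein by PPI
  expect_error(parse_formula("CBND(A, B) & PPI(A, B)"), class = "pl_bad_sort")
  expect_error(parse_formula("FD(Px))"), class = "pl_syntax_error")
})

test_that("parse/serialize round-trips random formulas structurally", {
  withr::with_seed(42, {
    for (i in 1:200) {
      f <- random_ground_formula(depth = sample(1:6, 1))
      g <- parse_formula(serialize_formula(f))
      expect_identical(protlogic:::fkey(g), protlogic:::fkey(f))
    }
  })
})

test_that("substitution instantiates variables and enforces its contracts", {
  r1 <- table1_rules$formula[[match("R1", table1_rules$id)]]
  s <- substitution(Px = pl_const("P53"))
  expect_equal(serialize_formula(apply_substitution(r1, s)),
               "FD(P53) -> (ST(P53) -> F(P53))")
  expect_true(is_ground(apply_substitution(r1, s)))

  r9 <- table1_rules$formula[[match("R9", table1_rules$id)]]
  expect_error(substitution(Px = pl_const("A"), Py = pl_const("A")),
               class = "pl_subst_not_injective")
  s2 <- substitution(Px = pl_const("A"), Py = pl_const("A"), injective = FALSE)
  expect_true(is_ground(apply_substitution(r9, s2)))

  expect_error(apply_substitution(r9, substitution(Px = pl_const("A"))),
               class = "pl_unbound_variable")
  expect_error(
    apply_substitution(r1, substitution(Px = pl_const("ATP", "ligand"))),
    class = "pl_bad_sort")

  r11 <- table1_rules$formula[[match("R11", table1_rules$id)]]
  out <- apply_substitution(r11, substitution(Px = pl_const("A"),
                                              Ly = pl_const("ATP", "ligand")))
  expect_equal(serialize_formula(out), "CBND(A, ATP) & F(A) -> AAS(A)")
})

test_that("grounding counts match brute-force substitution enumeration", {
  two_p_one_l <- list(pl_const("A"), pl_const("B"), pl_const("ATP", "ligand"))
  g <- ground_rules(table1_rules, two_p_one_l, injective = TRUE)
  for (id in table1_rules$id) {
    expect_equal(
      sum(g$rule_id == id),
      count_substitutions(table1_rules$formula[[match(id, table1_rules$id)]],
                          two_p_one_l, injective = TRUE),
      info = id)
  }
  # every rule here has an admissible substitution count of exactly 2
  expect_true(all(table(g$rule_id) == 2L))

  # and for a larger constant set, non-injectively
  four <- list(pl_const("A"), pl_const("B"), pl_const("C"),
               pl_const("ATP", "ligand"))
  g4 <- ground_rules(table1_rules, four, injective = FALSE)
  for (id in table1_rules$id) {
    expect_equal(
      sum(g4$rule_id == id),
      count_substitutions(table1_rules$formula[[match(id, table1_rules$id)]],
                          four, injective = FALSE),
      info = id)
  }

  # no ligand constants: the two CBND rules cannot ground
  gp <- ground_rules(table1_rules, list(pl_const("A"), pl_const("B")))
  expect_false(any(gp$rule_id %in% c("R4", "R11")))

  # one protein, injective: two-protein rules cannot ground
  g1 <- ground_rules(table1_rules, list(pl_const("A")))
  expect_false(any(g1$rule_id %in% c("R6", "R7", "R8", "R9", "R10", "R12")))
  expect_true(all(c("R1", "R2", "R3", "R5", "R13") %in% g1$rule_id))

  # deterministic order: same call twice gives identical tables
  expect_identical(ground_rules(table1_rules, two_p_one_l)$key, g$key)
})

test_that("subformula closure is a superset, counts nodes, and is idempotent", {
  f <- parse_formula("FD(A) -> (ST(A) -> F(A))")
  cl <- subformula_closure(list(f))
  expect_length(cl, 5L)
  expect_true(protlogic:::fkey(f) %in% names(cl))
  expect_setequal(names(cl),
                  c(protlogic:::fkey(f), "FD(A)", "ST(A) -> F(A)", "ST(A)", "F(A)"))

  a <- parse_formula("ST(A)")
  expect_length(subformula_closure(list(a)), 1L)

  withr::with_seed(7, {
    fs <- lapply(1:10, function(i) random_ground_formula(4))
    cl1 <- subformula_closure(fs)
    cl2 <- subformula_closure(cl1)
    expect_setequal(names(cl2), names(cl1))
    expect_true(all(vapply(fs, protlogic:::fkey, character(1)) %in% names(cl1)))
  })
})
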