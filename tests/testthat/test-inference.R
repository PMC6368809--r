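pf <- parse_formula

test_that("each inference rule fires on its pattern and only its pattern", {
  fd <- pf("FD(A)"); st <- pf("ST(A)"); f <- pf("F(A)")
  imp <- pf("FD(A) -> ST(A)")

  expect_equal(serialize_formula(apply_inference_rule("ModusPonens", list(fd, imp))),
               "ST(A)")
  expect_null(apply_inference_rule("ModusPonens", list(st, imp)))

  expect_equal(serialize_formula(
    apply_inference_rule("ModusTollens", list(pf("~ST(A)"), imp))), "~FD(A)")

  expect_equal(
    vapply(protlogic:::rule_conclusions("Simplification", list(pf("FD(A) & ST(A)"))),
           serialize_formula, character(1)),
    c("FD(A)", "ST(A)"))

  expect_equal(serialize_formula(
    apply_inference_rule("Conjunction", list(fd, st))), "FD(A) & ST(A)")

  expect_equal(serialize_formula(
    apply_inference_rule("DisjunctiveSyllogism",
                         list(pf("FD(A) | ST(A)"), pf("~FD(A)")))), "ST(A)")
  expect_null(apply_inference_rule("DisjunctiveSyllogism",
                                   list(pf("FD(A) | ST(A)"), pf("~F(A)"))))

  expect_equal(serialize_formula(
    apply_inference_rule("DisjunctiveAmplification", list(st),
                         universe = list(pf("FD(A) | ST(A)")))),
    "FD(A) | ST(A)")
  expect_null(apply_inference_rule("DisjunctiveAmplification", list(st),
                                   universe = list(pf("FD(A) | F(A)"))))

  expect_equal(serialize_formula(
    apply_inference_rule("Contradiction", list(pf("~FD(A) -> False")))), "FD(A)")

  expect_equal(serialize_formula(
    apply_inference_rule("ConditionalProof",
                         list(pf("FD(A) & ST(A)"),
                              pf("FD(A) -> (ST(A) -> F(A))")))), "F(A)")

  expect_equal(serialize_formula(
    apply_inference_rule("ProofByCases",
                         list(pf("FD(A) -> F(A)"), pf("ST(A) -> F(A)")))),
    "FD(A) | ST(A) -> F(A)")

  expect_equal(serialize_formula(
    apply_inference_rule("LawOfSyllogism",
                         list(pf("ST(A) -> AAS(A)"), pf("AAS(A) -> F(A)")))),
    "ST(A) -> F(A)")

  expect_error(apply_inference_rule("Abduction", list(fd)),
               class = "pl_unknown_rule")
  expect_error(apply_inference_rule("ModusPonens", list(fd)),
               class = "pl_bad_arity")
})

test_that("forward chaining reproduces the worked-example conclusions", {
  fx <- worked_example_fixtures()
  for (nm in names(fx)) {
    e <- fx[[nm]]
    fa <- derive_function_atoms(e$given, table1_rules, e$constants)
    expect_setequal(fa$atom, e$conclusions)
    for (p in fa$proof) {
      expect_true(check_proof(p, e$given, table1_rules)$valid, info = nm)
    }
  }
})

test_that("forward chaining honours its boundary contracts", {
  grounded <- ground_rules(table1_rules, list(pl_const("A")))
  # nothing given: the rule instances (and implications composed from them,
  # e.g. by Law of Syllogism) are proven, but no atom can be derived
  d0 <- forward_chain(list(), grounded)
  expect_true(all(unique(grounded$key) %in% derived_keys(d0)))
  expect_false(any(vapply(d0$derived, function(f) f$type == "atom", logical(1))))

  # a lone interaction premise licenses the disjunction but no bare F atom
  two <- list(pl_const("A"), pl_const("B"))
  g2 <- ground_rules(table1_rules, two)
  ppi <- pf("PPI(A, B)")
  d1 <- forward_chain(list(ppi), g2)
  expect_true("F(A) | F(B)" %in% derived_keys(d1))
  fa <- derive_function_atoms(list(ppi), table1_rules, two)
  expect_equal(nrow(fa), 0L)

  expect_error(forward_chain(list(table1_rules$formula[[1]]), grounded),
               class = "pl_not_ground")
})

test_that("the proof checker accepts the fixtures and localises tampering", {
  fx <- worked_example_fixtures()
  counts <- c(ex1 = 5L, ex2 = 13L, ex3 = 5L, ex4 = 9L)
  for (nm in names(fx)) {
    e <- fx[[nm]]
    ck <- check_proof(e$proof, e$given, table1_rules)
    expect_true(ck$valid, info = nm)
    expect_equal(nrow(e$proof), counts[[nm]], info = nm)
    expect_equal(sum(ck$line_ok), counts[[nm]], info = nm)
  }

  bad <- fx$ex1$proof
  bad$antecedents[[5]] <- c(2L, 4L)
  ck <- check_proof(bad, fx$ex1$given, table1_rules)
  expect_false(ck$valid)
  expect_equal(ck$first_invalid, 5L)

  # a line quoting a premise that was never given
  bad2 <- fx$ex3$proof
  bad2$kind[[1]] <- "given"
  ck2 <- check_proof(bad2, list(pf("FD(Px)")), table1_rules)
  expect_equal(ck2$first_invalid, 1L)
})

test_that("proofs round-trip through JSON lines", {
  fx <- worked_example_fixtures()
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_proof(fx$ex2$proof, path)
  back <- read_proof(path)
  expect_equal(back$text, fx$ex2$proof$text)
  expect_equal(back$kind, fx$ex2$proof$kind)
  expect_equal(back$antecedents, fx$ex2$proof$antecedents)
  expect_true(check_proof(back, fx$ex2$given, table1_rules)$valid)
})

test_that("truth-table entailment agrees with hand-checked cases", {
  r1a <- pf("FD(A) -> (ST(A) -> F(A))")
  expect_true(entails_bruteforce(list(pf("FD(A)"), pf("ST(A)"), r1a), pf("F(A)")))
  expect_false(entails_bruteforce(list(pf("FD(A)")), pf("F(A)")))
  expect_true(entails_bruteforce(list(), pf("ST(A) | ~ST(A)")))
  expect_false(entails_bruteforce(list(), pf("ST(A)")))
  expect_true(entails_bruteforce(list(pf("~ST(A) -> False")), pf("ST(A)")))
  # the atom cap guards the exponential enumeration
  big <- lapply(c("A", "B", "C"), function(p) {
    lapply(c("FD", "ST", "AAS", "F", "PCF", "PPI"), function(pr) {
      if (pr %in% c("PCF", "PPI")) pf(sprintf("%s(%s, %s)", pr, p,
                                              setdiff(c("A", "B"), p)[1]))
      else pf(sprintf("%s(%s)", pr, p))
    })
  })
  expect_error(entails_bruteforce(unlist(big, recursive = FALSE), pf("F(A)")),
               class = "pl_atom_cap")
})

test_that("forward chaining is sound against the truth-table oracle", {
  for (seed in 1:60) {
    inst <- random_instance(seed)
    d <- forward_chain(inst$given, inst$grounded)
    prem <- c(inst$given, inst$grounded$formula)
    verdicts <- entails_bruteforce(prem, unname(d$derived))
    expect_true(all(verdicts), info = paste("seed", seed))
  }
})

test_that("chaining is monotone, deterministic, and terminates within the universe", {
  for (seed in 101:130) {
    inst <- random_instance(seed)
    d1 <- forward_chain(inst$given, inst$grounded)
    extra <- withr::with_seed(seed + 1000, {
      p <- pl_const(sample(c("P1", "P2"), 1))
      pl_atom(sample(c("FD", "ST", "AAS"), 1), list(p))
    })
    d2 <- forward_chain(c(inst$given, list(extra)), inst$grounded)
    expect_true(all(derived_keys(d1) %in% derived_keys(d2)),
                info = paste("seed", seed))

    d1b <- forward_chain(inst$given, inst$grounded)
    expect_identical(derived_keys(d1), derived_keys(d1b))
    expect_identical(d1$iterations, d1b$iterations)
    expect_lte(d1$iterations, length(d1$universe))
  }
})

test_that("every proof extracted from a derivation validates", {
  for (seed in c(7, 21, 33)) {
    inst <- random_instance(seed)
    d <- forward_chain(inst$given, inst$grounded)
    rules_tbl <- tibble::tibble(id = inst$grounded$rule_id,
                                formula = inst$grounded$formula)
    for (k in derived_keys(d)) {
      pr <- derivation_proof(d, k)
      expect_true(check_proof(pr, inst$given, rules_tbl)$valid,
                  info = paste(seed, k))
    }
  }
})
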