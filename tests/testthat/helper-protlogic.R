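# Shared fixtures and independent oracles used across the suite.

table1_rules <- spec_rules()

# Random ground formula generator for round-trip properties.
random_ground_formula <- function(depth = 4L) {
  consts <- list(p = c("A", "B", "C"), l = c("L1", "L2"))
  rand_atom <- function() {
    pred <- sample(names(protlogic:::pl_signatures), 1L)
    sig <- protlogic:::pl_signatures[[pred]]
    args <- lapply(sig, function(s) {
      pl_const(sample(if (s == "protein") consts$p else consts$l, 1L), s)
    })
    pl_atom(pred, args)
  }
  build <- function(d) {
    if (d <= 0L || stats::runif(1) < 0.3) {
      if (stats::runif(1) < 0.05) return(pl_false())
      return(rand_atom())
    }
    switch(sample(4L, 1L),
           pl_not(build(d - 1L)),
           pl_and(build(d - 1L), build(d - 1L)),
           pl_or(build(d - 1L), build(d - 1L)),
           pl_implies(build(d - 1L), build(d - 1L)))
  }
  build(depth)
}

# Independent brute-force enumeration of admissible substitutions for one
# rule: every assignment of constants to the rule's variables, filtered for
# sort agreement and (optionally) injectivity. Used as the grounding-count
# oracle; deliberately unrelated to ground_rules' odometer.
count_substitutions <- function(formula, constants, injective = TRUE) {
  vars <- formula_vars(formula)
  if (length(vars) == 0L) return(1L)
  names <- vapply(constants, function(t) t$name, character(1))
  sorts <- vapply(constants, function(t) t$sort, character(1))
  grid <- expand.grid(rep(list(seq_along(constants)), length(vars)))
  ok <- 0L
  for (r in seq_len(nrow(grid))) {
    idx <- as.integer(grid[r, ])
    if (any(sorts[idx] != vapply(vars, function(v) v$sort, character(1)))) next
    if (injective && anyDuplicated(names[idx])) next
    ok <- ok + 1L
  }
  ok
}

# Random small chaining instance: a handful of rules grounded over 2-3
# proteins (sometimes a ligand) plus random ground given atoms, trimmed so
# the truth-table oracle stays within its atom cap.
random_instance <- function(seed, atom_cap = 16L) {
  withr::with_seed(seed, {
    consts <- lapply(seq_len(sample(2:3, 1L)), function(i) pl_const(paste0("P", i)))
    if (stats::runif(1) < 0.4) consts <- c(consts, list(pl_const("L1", "ligand")))
    prots <- Filter(function(t) t$sort == "protein", consts)
    rsel <- table1_rules[sort(sample(nrow(table1_rules), sample(3:6, 1L))), ]
    grounded <- ground_rules(rsel, consts)
    given <- lapply(seq_len(sample(1:4, 1L)), function(i) {
      pred <- sample(c("FD", "ST", "AAS", "F", "PPI", "NCBND", "PCF", "CBND"), 1L)
      sig <- protlogic:::pl_signatures[[pred]]
      args <- lapply(sig, function(s) {
        pool <- if (s == "protein") prots else list(pl_const("L1", "ligand"))
        pool[[sample(length(pool), 1L)]]
      })
      pl_atom(pred, args)
    })
    n_atoms <- function() {
      fs <- c(given, grounded$formula)
      length(unique(unlist(lapply(fs, function(f)
        vapply(protlogic:::formula_atoms(f), protlogic:::fkey, character(1))))))
    }
    while (nrow(grounded) > 0L && n_atoms() > atom_cap) {
      grounded <- grounded[-nrow(grounded), ]
    }
    list(given = given, grounded = grounded)
  })
}

derived_keys <- function(deriv) names(deriv$derived)

# Small handcrafted study lexicon shared by extraction/pipeline tests.
tiny_lexicon <- function() {
  as_lexicon(tibble::tibble(
    entry_id = c("PU1", "PA", "FOLD", "STRUCT", "AASQ", "APO"),
    pattern = c("PU1", "PA", "folding", "structure",
                "amino acid sequence|sequence", "apoptosis"),
    payload_kind = c("protein", "protein", "template", "template",
                     "template", "category"),
    payload_value = c("PU1", "PA", "FD(protein)", "ST(protein)",
                      "AAS(protein)", "GO:0042981")
  ))
}

tiny_corpus <- function(texts, protein = "PU1") {
  tibble::tibble(doc_id = sprintf("d%02d", seq_along(texts)),
                 protein_ids = rep(list(protein), length(texts)),
                 text = texts)
}
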