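# The ten standard inference rules, forward chaining, and proofs.

#' @export
inference_rule_names <- c(
  "ModusTollens", "ModusPonens", "Simplification", "Conjunction",
  "DisjunctiveSyllogism", "DisjunctiveAmplification", "Contradiction",
  "ConditionalProof", "ProofByCases", "LawOfSyllogism"
)

inference_rule_arity <- c(
  ModusTollens = 2L, ModusPonens = 2L, Simplification = 1L, Conjunction = 2L,
  DisjunctiveSyllogism = 2L, DisjunctiveAmplification = 1L, Contradiction = 1L,
  ConditionalProof = 2L, ProofByCases = 2L, LawOfSyllogism = 2L
)

# All conclusions a rule licenses from an ordered premise list. Binary rules
# are tried in both premise orders (the premises of a rule application are a
# set; tables cite them in either order). Simplification yields both
# conjuncts; Disjunctive Amplification targets disjunctions drawn from
# `universe` (either side may be the premise). Returned conclusions are
# deduplicated by structural identity.
rule_conclusions <- function(rule_name, premises, universe = NULL) {
  if (!rule_name %in% inference_rule_names) {
    abort(sprintf("unknown inference rule '%s'", rule_name), class = "pl_unknown_rule")
  }
  n <- inference_rule_arity[[rule_name]]
  if (length(premises) != n) {
    abort(sprintf("%s takes %d premise(s), got %d", rule_name, n, length(premises)),
          class = "pl_bad_arity")
  }
  a <- premises[[1]]
  b <- if (n == 2L) premises[[2]] else NULL
  orders <- if (n == 2L) list(list(a, b), list(b, a)) else list(list(a))
  out <- list()
  add <- function(f) out[[length(out) + 1L]] <<- f
  for (o in orders) {
    p <- o[[1]]; q <- if (length(o) == 2L) o[[2]] else NULL
    switch(rule_name,
      ModusPonens = {  # p, p -> q  =>  q
        if (q$type == "implies" && fkey(q$lhs) == fkey(p)) add(q$rhs)
      },
      ModusTollens = {  # ~q, p -> q  =>  ~p
        if (p$type == "not" && q$type == "implies" && fkey(q$rhs) == fkey(p$x)) {
          add(pl_not(q$lhs))
        }
      },
      Simplification = {  # p & q  =>  p (and, symmetrically, q)
        if (p$type == "and") { add(p$lhs); add(p$rhs) }
      },
      Conjunction = {  # p, q  =>  p & q
        add(pl_and(p, q))
      },
      DisjunctiveSyllogism = {  # p | q, ~p  =>  q
        if (p$type == "or" && q$type == "not" && fkey(p$lhs) == fkey(q$x)) {
          add(p$rhs)
        }
      },
      DisjunctiveAmplification = {  # p  =>  p | q, q from the universe
        pk <- fkey(p)
        for (u in universe) {
          if (u$type == "or" && (fkey(u$lhs) == pk || fkey(u$rhs) == pk)) add(u)
        }
      },
      Contradiction = {  # ~p -> False  =>  p
        if (p$type == "implies" && p$rhs$type == "false" && p$lhs$type == "not") {
          add(p$lhs$x)
        }
      },
      ConditionalProof = {  # p & q, p -> (q -> r)  =>  r
        if (p$type == "and" && q$type == "implies" && q$rhs$type == "implies" &&
            fkey(q$lhs) == fkey(p$lhs) && fkey(q$rhs$lhs) == fkey(p$rhs)) {
          add(q$rhs$rhs)
        }
      },
      ProofByCases = {  # p -> r, q -> r  =>  (p | q) -> r
        if (p$type == "implies" && q$type == "implies" &&
            fkey(p$rhs) == fkey(q$rhs)) {
          add(pl_implies(pl_or(p$lhs, q$lhs), p$rhs))
        }
      },
      LawOfSyllogism = {  # p -> q, q -> r  =>  p -> r
        if (p$type == "implies" && q$type == "implies" &&
            fkey(p$rhs) == fkey(q$lhs)) {
          add(pl_implies(p$lhs, q$rhs))
        }
      }
    )
  }
  if (length(out) == 0L) return(list())
  out[!duplicated(fkeys(out))]
}

#' Apply a single inference rule
#'
#' Applies one of the ten standard propositional inference rules to ground
#' premise formulas and returns the conclusion, or `NULL` when the premises
#' do not match the rule's pattern. Binary rules accept their premises in
#' either order. `Simplification` licenses both conjuncts; the first
#' (`p` from `p & q`) is returned. `DisjunctiveAmplification` needs a
#' `universe` of candidate disjunctions to amplify into.
#'
#' @param rule_name One of `r paste(inference_rule_names, collapse = ", ")`.
#' @param premises List of ground `pl_formula` (length 1 or 2 per rule).
#' @param universe Optional list of formulas; used only by
#'   `DisjunctiveAmplification`.
#' @return A ground `pl_formula`, or `NULL` if the pattern does not match.
#' @examples
#' a <- parse_formula("FD(A)")
#' r <- parse_formula("FD(A) -> ST(A)")
#' apply_inference_rule("ModusPonens", list(a, r))
#' @export
apply_inference_rule <- function(rule_name, premises, universe = NULL) {
  out <- rule_conclusions(rule_name, premises, universe)
  if (length(out) == 0L) NULL else out[[1]]
}

# ---- forward chaining -------------------------------------------------------

#' Forward-chain ground rules and given premises
#'
#' Repeatedly applies the ten inference rules to the set of proven formulas
#' (the given premises plus the ground specification-rule instances) until
#' no new formula is derived. Conclusions are admitted only if they lie in
#' the finite universe `subformula_closure(given + rule formulas)`, which
#' bounds the otherwise unbounded Conjunction and Disjunctive Amplification
#' rules and guarantees termination in at most `|universe|` iterations.
#' Within an iteration every rule is applied to every admissible premise
#' tuple drawn from the previous iteration's formulas; the first derivation
#' of a formula provides its recorded justification. The procedure is
#' deterministic given input order.
#'
#' @param given List of ground `pl_formula` (typically atoms extracted from
#'   text as given premises).
#' @param rules Grounded rules: a tibble from [ground_rules()] (columns
#'   `rule_id`, `formula`), or a list of ground formulas.
#' @param max_iterations Iteration cap (the fixpoint is normally reached
#'   much earlier).
#' @return A `pl_derivation`: list with `derived` (named list of formulas,
#'   insertion order), `justifications`, `iterations`, `universe`,
#'   `given_keys`, `rule_keys`. Use [derivation_proof()] to extract a
#'   checkable proof for any derived formula.
#' @export
forward_chain <- function(given, rules, max_iterations = 100L) {
  if (is_pl_formula(given)) given <- list(given)
  for (f in given) {
    if (!is_ground(f)) abort("given premises must be ground", class = "pl_not_ground")
  }
  if (is.data.frame(rules)) {
    rule_ids <- rules$rule_id %||% rules$id
    rule_fs <- rules$formula
  } else {
    rule_fs <- rules
    rule_ids <- names(rules) %||% rep("rule", length(rules))
  }
  for (f in rule_fs) {
    if (!is_ground(f)) abort("rules passed to forward_chain must be ground",
                             class = "pl_not_ground")
  }
  if (max_iterations < 1L) abort("max_iterations must be >= 1", class = "pl_bad_arg")

  universe <- subformula_closure(c(given, rule_fs))
  ukeys <- names(universe)
  u_conj <- Filter(function(f) f$type == "and", universe)
  u_disj <- Filter(function(f) f$type == "or", universe)
  u_impl <- Filter(function(f) f$type == "implies", universe)

  derived <- list()        # key -> formula, insertion order
  just <- list()           # key -> list(kind, rule, antecedents = keys)
  add <- function(f, kind, rule, ants = character(0)) {
    k <- fkey(f)
    if (!is.null(just[[k]])) return(FALSE)
    derived[[k]] <<- f
    just[[k]] <<- list(kind = kind, rule = rule, antecedents = ants)
    TRUE
  }
  for (f in given) add(f, "given", "given")
  for (i in seq_along(rule_fs)) add(rule_fs[[i]], "specification_rule", rule_ids[[i]])

  iterations <- 0L
  repeat {
    if (iterations >= max_iterations) break
    iterations <- iterations + 1L
    snap <- derived  # rules fire from the previous iteration's formulas
    has <- function(k) !is.null(snap[[k]])
    snap_impl <- Filter(function(f) f$type == "implies", snap)
    snap_conj <- Filter(function(f) f$type == "and", snap)
    snap_disj <- Filter(function(f) f$type == "or", snap)
    grew <- FALSE
    note <- function(f, rule, ants) {
      k <- fkey(f)
      if (k %in% ukeys && is.null(just[[k]])) {
        grew <<- add(f, "inference_rule", rule, ants) || grew
      }
    }
    # ModusPonens: p, p -> q => q
    for (d in snap_impl) {
      lk <- fkey(d$lhs)
      if (has(lk)) note(d$rhs, "ModusPonens", c(lk, fkey(d)))
    }
    # ModusTollens: ~q, p -> q => ~p
    for (d in snap_impl) {
      nq <- pl_not(d$rhs); nqk <- fkey(nq)
      if (has(nqk)) note(pl_not(d$lhs), "ModusTollens", c(nqk, fkey(d)))
    }
    # Simplification: p & q => p, q
    for (d in snap_conj) {
      dk <- fkey(d)
      note(d$lhs, "Simplification", dk)
      note(d$rhs, "Simplification", dk)
    }
    # Conjunction: p, q => p & q (targets drawn from the universe)
    for (u in u_conj) {
      lk <- fkey(u$lhs); rk <- fkey(u$rhs)
      if (has(lk) && has(rk)) note(u, "Conjunction", c(lk, rk))
    }
    # DisjunctiveSyllogism: p | q, ~p => q
    for (d in snap_disj) {
      np <- pl_not(d$lhs); npk <- fkey(np)
      if (has(npk)) note(d$rhs, "DisjunctiveSyllogism", c(fkey(d), npk))
    }
    # DisjunctiveAmplification: p => p | q (targets from the universe)
    for (u in u_disj) {
      lk <- fkey(u$lhs); rk <- fkey(u$rhs)
      if (has(lk)) note(u, "DisjunctiveAmplification", lk)
      else if (has(rk)) note(u, "DisjunctiveAmplification", rk)
    }
    # Contradiction: ~p -> False => p
    for (d in snap_impl) {
      if (d$rhs$type == "false" && d$lhs$type == "not") {
        note(d$lhs$x, "Contradiction", fkey(d))
      }
    }
    # ConditionalProof: p & q, p -> (q -> r) => r
    for (d in snap_impl) {
      if (d$rhs$type == "implies") {
        conj <- pl_and(d$lhs, d$rhs$lhs); ck <- fkey(conj)
        if (has(ck)) note(d$rhs$rhs, "ConditionalProof", c(ck, fkey(d)))
      }
    }
    # ProofByCases: p -> r, q -> r => (p | q) -> r (targets from the universe)
    for (u in u_impl) {
      if (u$lhs$type == "or") {
        k1 <- fkey(pl_implies(u$lhs$lhs, u$rhs))
        k2 <- fkey(pl_implies(u$lhs$rhs, u$rhs))
        if (has(k1) && has(k2)) note(u, "ProofByCases", c(k1, k2))
      }
    }
    # LawOfSyllogism: p -> q, q -> r => p -> r (targets from the universe)
    for (u in u_impl) {
      uk <- fkey(u)
      if (!is.null(just[[uk]])) next
      for (d in snap_impl) {
        if (fkey(d$lhs) == fkey(u$lhs)) {
          k2 <- fkey(pl_implies(d$rhs, u$rhs))
          if (has(k2)) { note(u, "LawOfSyllogism", c(fkey(d), k2)); break }
        }
      }
    }
    if (!grew) break
  }

  structure(list(
    derived = derived,
    justifications = just,
    iterations = iterations,
    universe = universe,
    given_keys = fkeys(given),
    rule_keys = fkeys(rule_fs)
  ), class = "pl_derivation")
}

#' @export
print.pl_derivation <- function(x, ...) {
  cat(sprintf("<derivation> %d formulas derived (%d given, %d rule instances) in %d iteration(s); universe %d\n",
              length(x$derived), length(unique(x$given_keys)),
              length(unique(x$rule_keys)), x$iterations, length(x$universe)))
  invisible(x)
}

#' Derived function atoms with proofs
#'
#' Grounds the specification rules over the constants, forward-chains from
#' the given premises, and returns every newly derived atom with predicate
#' `F` (a protein function) together with a checkable proof. `F` atoms that
#' were themselves given premises are excluded: they carry explicit, not
#' inferred, evidence.
#'
#' @param given List of ground atom formulas (the given premises).
#' @param rules Specification rules tibble from [parse_rule_file()].
#' @param constants Constants to ground over (list of [pl_const()] or a
#'   `name`/`sort` data frame); defaults to the constants appearing in
#'   `given`.
#' @param injective Injective grounding (default on).
#' @param max_iterations Passed to [forward_chain()].
#' @return A tibble with columns `atom` (text), `protein` (the constant
#'   name), `formula` (list) and `proof` (list of `pl_proof`).
#' @export
derive_function_atoms <- function(given, rules, constants = NULL,
                                  injective = TRUE, max_iterations = 100L) {
  if (is_pl_formula(given)) given <- list(given)
  if (is.null(constants)) constants <- formula_constants(given)
  grounded <- ground_rules(rules, constants, injective = injective)
  deriv <- forward_chain(given, grounded, max_iterations = max_iterations)
  given_keys <- fkeys(given)
  keys <- names(deriv$derived)
  hits <- keys[vapply(deriv$derived, function(f) f$type == "atom" && f$pred == "F",
                      logical(1)) & !keys %in% given_keys]
  tibble::tibble(
    atom = vapply(hits, function(k) serialize_formula(deriv$derived[[k]]), character(1)),
    protein = vapply(hits, function(k) deriv$derived[[k]]$args[[1]]$name, character(1)),
    formula = lapply(hits, function(k) deriv$derived[[k]]),
    proof = lapply(hits, function(k) derivation_proof(deriv, deriv$derived[[k]]))
  )
}
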