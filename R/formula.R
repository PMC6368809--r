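#' @importFrom rlang abort warn %||%
NULL

# Predicate signatures: argument sorts, in order. Arity is fixed per predicate.
pl_signatures <- list(
  ST    = "protein",
  FD    = "protein",
  F     = "protein",
  AAS   = "protein",
  CBND  = c("protein", "ligand"),
  PPI   = c("protein", "protein"),
  NCBND = c("protein", "protein"),
  PCF   = c("protein", "protein")
)

pl_sorts <- c("protein", "ligand")

#' Terms: constants and variables
#'
#' A term is an argument of an atom: either a constant symbol (a concrete
#' protein or ligand name extracted from text) or a variable (a placeholder
#' in a specification rule, implicitly universally quantified). Every term
#' carries a sort, `"protein"` or `"ligand"`; sorts are fixed by the
#' predicate signature of the position a term occupies and are never
#' inferred from the name.
#'
#' @param name Non-empty identifier string.
#' @param sort `"protein"` or `"ligand"`.
#' @return A `pl_term` object.
#' @examples
#' pl_const("P53", "protein")
#' pl_var("Px", "protein")
#' @export
pl_const <- function(name, sort = "protein") new_term(name, sort, var = FALSE)

#' @rdname pl_const
#' @export
pl_var <- function(name, sort = "protein") new_term(name, sort, var = TRUE)

new_term <- function(name, sort, var) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort("term name must be a non-empty string", class = "pl_bad_term")
  }
  if (!sort %in% pl_sorts) {
    abort(sprintf("unknown sort '%s' (expected protein or ligand)", sort),
          class = "pl_bad_sort")
  }
  structure(list(name = name, sort = sort, var = var), class = "pl_term")
}

is_pl_term <- function(x) inherits(x, "pl_term")

# ---- formula nodes ----------------------------------------------------------

new_formula <- function(type, ...) {
  structure(c(list(type = type), list(...)), class = "pl_formula")
}

#' Build logic formulas
#'
#' Formulas are finite trees over atoms with negation (`~`), conjunction
#' (`&`), disjunction (`|`) and implication (`->`), plus the always-false
#' constant `False` used by the Contradiction inference rule. Equality is
#' structural on the tree as written: connectives stay binary and argument
#' order is preserved (no associative/commutative normalisation), because
#' the inference-rule patterns are directional.
#'
#' @param predicate Predicate name; one of `ST`, `FD`, `F`, `AAS`, `CBND`,
#'   `PPI`, `NCBND`, `PCF`.
#' @param ... Terms created with [pl_const()] or [pl_var()]; their number
#'   and sorts must match the predicate signature.
#' @param x,lhs,rhs Sub-formulas.
#' @return A `pl_formula` object.
#' @examples
#' a <- pl_atom("FD", pl_const("P53"))
#' b <- pl_atom("ST", pl_const("P53"))
#' pl_implies(a, b)
#' @export
pl_atom <- function(predicate, ...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1]]) && !is_pl_term(args[[1]])) {
    args <- args[[1]]
  }
  sig <- pl_signatures[[predicate]]
  if (is.null(sig)) {
    abort(sprintf("unknown predicate '%s'", predicate), class = "pl_unknown_predicate")
  }
  if (length(args) != length(sig)) {
    abort(sprintf("%s takes %d argument(s), got %d", predicate, length(sig), length(args)),
          class = "pl_bad_arity")
  }
  for (i in seq_along(args)) {
    if (!is_pl_term(args[[i]])) abort("atom arguments must be pl_term objects",
                                      class = "pl_bad_term")
    if (args[[i]]$sort != sig[[i]]) {
      abort(sprintf("argument %d of %s must have sort %s, got %s (%s)",
                    i, predicate, sig[[i]], args[[i]]$sort, args[[i]]$name),
            class = "pl_bad_sort")
    }
  }
  new_formula("atom", pred = predicate, args = args)
}

#' @rdname pl_atom
#' @export
pl_false <- function() new_formula("false")

#' @rdname pl_atom
#' @export
pl_not <- function(x) new_formula("not", x = check_formula(x))

#' @rdname pl_atom
#' @export
pl_and <- function(lhs, rhs) new_formula("and", lhs = check_formula(lhs), rhs = check_formula(rhs))

#' @rdname pl_atom
#' @export
pl_or <- function(lhs, rhs) new_formula("or", lhs = check_formula(lhs), rhs = check_formula(rhs))

#' @rdname pl_atom
#' @export
pl_implies <- function(lhs, rhs) new_formula("implies", lhs = check_formula(lhs), rhs = check_formula(rhs))

check_formula <- function(x) {
  if (!inherits(x, "pl_formula")) abort("expected a pl_formula", class = "pl_bad_formula")
  x
}

is_pl_formula <- function(x) inherits(x, "pl_formula")

# ---- serialisation ----------------------------------------------------------

# Precedence levels: -> 1 (right-assoc), | 2, & 3, ~ 4, atom/False 5.
# A compound consequent of -> is parenthesised even though -> is
# right-associative, mirroring how nested rules are conventionally printed.
ser_node <- function(f, ctx, marked) {
  switch(f$type,
    atom = {
      args <- vapply(f$args, function(t) {
        if (marked && t$var) paste0("?", t$name) else t$name
      }, character(1))
      paste0(f$pred, "(", paste(args, collapse = ", "), ")")
    },
    false = "False",
    not = paste0("~", ser_node(f$x, 4L, marked)),
    and = wrap(paste(ser_node(f$lhs, 3L, marked), "&", ser_node(f$rhs, 4L, marked)), 3L, ctx),
    or  = wrap(paste(ser_node(f$lhs, 2L, marked), "|", ser_node(f$rhs, 3L, marked)), 2L, ctx),
    implies = {
      rhs_txt <- ser_node(f$rhs, 1L, marked)
      if (f$rhs$type %in% c("implies", "and", "or", "not")) {
        rhs_txt <- paste0("(", rhs_txt, ")")
      }
      wrap(paste(ser_node(f$lhs, 2L, marked), "->", rhs_txt), 1L, ctx)
    },
    abort("corrupt formula node", class = "pl_bad_formula")
  )
}

wrap <- function(txt, prec, ctx) if (prec < ctx) paste0("(", txt, ")") else txt

#' Serialize a formula to its DSL text
#'
#' Produces the canonical ASCII spelling (`~`, `&`, `|`, `->`) with minimal
#' parentheses under the grammar's precedence; [parse_formula()] of the
#' result reproduces the formula exactly (round-trip).
#'
#' @param f A `pl_formula`.
#' @return A single string.
#' @export
serialize_formula <- function(f) ser_node(check_formula(f), 1L, marked = FALSE)

# Internal identity key: like serialize_formula but variables are marked,
# so a variable Px and a constant Px never collide.
fkey <- function(f) ser_node(f, 1L, marked = TRUE)

fkeys <- function(fs) vapply(fs, fkey, character(1))

#' @export
print.pl_formula <- function(x, ...) {
  cat("<formula> ", serialize_formula(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.pl_formula <- function(x, ...) serialize_formula(x)

#' @export
print.pl_term <- function(x, ...) {
  cat(sprintf("<%s %s> %s\n", if (x$var) "var" else "const", x$sort, x$name))
  invisible(x)
}

# ---- structure queries ------------------------------------------------------

walk_formula <- function(f, fn) {
  fn(f)
  switch(f$type,
    not = walk_formula(f$x, fn),
    and = , or = , implies = { walk_formula(f$lhs, fn); walk_formula(f$rhs, fn) },
    NULL)
  invisible(NULL)
}

#' Variables of a formula
#'
#' @param f A `pl_formula`.
#' @return A list of `pl_term` variables in order of first appearance.
#' @export
formula_vars <- function(f) {
  seen <- character(0)
  out <- list()
  walk_formula(check_formula(f), function(n) {
    if (n$type == "atom") {
      for (t in n$args) {
        if (t$var && !t$name %in% seen) {
          seen <<- c(seen, t$name)
          out[[length(out) + 1L]] <<- t
        }
      }
    }
  })
  out
}

#' @rdname formula_vars
#' @export
is_ground <- function(f) length(formula_vars(f)) == 0L

formula_atoms <- function(f) {
  out <- list()
  keys <- character(0)
  walk_formula(f, function(n) {
    if (n$type == "atom") {
      k <- fkey(n)
      if (!k %in% keys) {
        keys <<- c(keys, k)
        out[[length(out) + 1L]] <<- n
      }
    }
  })
  out
}

formula_constants <- function(fs) {
  if (is_pl_formula(fs)) fs <- list(fs)
  seen <- character(0)
  out <- list()
  for (f in fs) {
    walk_formula(f, function(n) {
      if (n$type == "atom") {
        for (t in n$args) {
          if (!t$var && !t$name %in% seen) {
            seen <<- c(seen, t$name)
            out[[length(out) + 1L]] <<- t
          }
        }
      }
    })
  }
  out
}

#' Subformula closure
#'
#' Returns the set of all subformulas (every node of every parse tree) of
#' the input formulas, deduplicated structurally, in deterministic order
#' (input order, then preorder within each tree). The closure is the finite
#' universe that bounds forward chaining: conclusions outside it are never
#' admitted, which makes the chaining terminate.
#'
#' @param formulas A list of `pl_formula` objects (or a single formula).
#' @return A list of `pl_formula`, a superset of the input, closed under
#'   taking immediate subformulas. Idempotent.
#' @export
subformula_closure <- function(formulas) {
  if (is_pl_formula(formulas)) formulas <- list(formulas)
  keys <- character(0)
  out <- list()
  for (f in formulas) {
    walk_formula(check_formula(f), function(n) {
      k <- fkey(n)
      if (!k %in% keys) {
        keys <<- c(keys, k)
        out[[length(out) + 1L]] <<- n
      }
    })
  }
  names(out) <- keys
  out
}

# ---- substitution -----------------------------------------------------------

#' Substitutions: variable-to-constant maps
#'
#' A substitution instantiates rule variables with constant symbols. It is
#' sort-respecting (protein variables take protein constants, ligand
#' variables ligand constants). With `injective = TRUE` (the default used
#' in grounding), distinct variables must map to distinct constants, which
#' avoids degenerate self-instantiations of two-protein rules.
#'
#' @param ... Named arguments, variable name = `pl_const()` value.
#' @param injective Require distinct constants for distinct variables.
#' @return A `pl_subst` object.
#' @examples
#' substitution(Px = pl_const("P53"), injective = TRUE)
#' @export
substitution <- function(..., injective = TRUE) {
  mapping <- list(...)
  if (length(mapping) == 1L && is.list(mapping[[1]]) && !is_pl_term(mapping[[1]])) {
    mapping <- mapping[[1]]
  }
  if (length(mapping) && (is.null(names(mapping)) || any(!nzchar(names(mapping))))) {
    abort("substitution entries must be named by variable", class = "pl_bad_subst")
  }
  for (t in mapping) {
    if (!is_pl_term(t) || t$var) {
      abort("substitution values must be constant terms", class = "pl_bad_subst")
    }
  }
  if (injective) {
    vals <- vapply(mapping, function(t) t$name, character(1))
    if (anyDuplicated(vals)) {
      abort("injective substitution maps distinct variables to the same constant",
            class = "pl_subst_not_injective")
    }
  }
  structure(list(mapping = mapping, injective = injective), class = "pl_subst")
}

#' Apply a substitution to a formula
#'
#' @param f A `pl_formula`; every variable it contains must be in the
#'   substitution's domain.
#' @param s A [substitution()].
#' @return The ground formula with variables replaced; structure otherwise
#'   unchanged.
#' @export
apply_substitution <- function(f, s) {
  check_formula(f)
  if (!inherits(s, "pl_subst")) abort("expected a pl_subst", class = "pl_bad_subst")
  subst_node(f, s$mapping)
}

subst_node <- function(f, m) {
  switch(f$type,
    atom = {
      args <- lapply(f$args, function(t) {
        if (!t$var) return(t)
        r <- m[[t$name]]
        if (is.null(r)) {
          abort(sprintf("unbound variable '%s'", t$name), class = "pl_unbound_variable")
        }
        if (r$sort != t$sort) {
          abort(sprintf("sort mismatch: variable %s (%s) mapped to %s (%s)",
                        t$name, t$sort, r$name, r$sort), class = "pl_bad_sort")
        }
        r
      })
      new_formula("atom", pred = f$pred, args = args)
    },
    false = f,
    not = new_formula("not", x = subst_node(f$x, m)),
    new_formula(f$type, lhs = subst_node(f$lhs, m), rhs = subst_node(f$rhs, m))
  )
}

# ---- pattern matching -------------------------------------------------------

# Match a (possibly variable-bearing) pattern against a ground formula.
# Returns a named list of bindings (variable name -> constant term) or NULL.
# With commute = TRUE, conjunction and disjunction nodes may match with
# their operands swapped: rule bodies are universally quantified and the
# connectives are commutative, so an instance that commutes a conjunct is
# still an instance of the rule (inference-rule patterns, by contrast, are
# matched structurally as written).
match_formula <- function(pattern, ground, bindings = list(), commute = FALSE) {
  res <- match_formula_all(pattern, ground, bindings, commute)
  if (length(res)) res[[1]] else NULL
}

# Full backtracking enumeration of consistent bindings (a locally successful
# operand order can still fail globally, so all alternatives are explored).
match_formula_all <- function(pattern, ground, bindings, commute) {
  if (pattern$type != ground$type) return(list())
  switch(pattern$type,
    false = list(bindings),
    atom = {
      if (pattern$pred != ground$pred) return(list())
      for (i in seq_along(pattern$args)) {
        pt <- pattern$args[[i]]; gt <- ground$args[[i]]
        if (pt$var) {
          b <- bindings[[pt$name]]
          if (is.null(b)) {
            if (pt$sort != gt$sort) return(list())
            bindings[[pt$name]] <- gt
          } else if (b$name != gt$name) return(list())
        } else if (pt$name != gt$name || pt$sort != gt$sort) return(list())
      }
      list(bindings)
    },
    not = match_formula_all(pattern$x, ground$x, bindings, commute),
    {
      out <- list()
      for (b1 in match_formula_all(pattern$lhs, ground$lhs, bindings, commute)) {
        out <- c(out, match_formula_all(pattern$rhs, ground$rhs, b1, commute))
      }
      if (commute && pattern$type %in% c("and", "or")) {
        for (b1 in match_formula_all(pattern$lhs, ground$rhs, bindings, commute)) {
          out <- c(out, match_formula_all(pattern$rhs, ground$lhs, b1, commute))
        }
      }
      out
    }
  )
}

is_instance_of <- function(ground, pattern, commute = TRUE) {
  !is.null(match_formula(pattern, ground, commute = commute))
}

# ---- grounding --------------------------------------------------------------

as_constant_list <- function(constants) {
  if (is.data.frame(constants)) {
    constants <- Map(pl_const, constants$name, constants$sort)
  } else if (is_pl_term(constants)) {
    constants <- list(constants)
  }
  for (t in constants) {
    if (!is_pl_term(t) || t$var) abort("constants must be non-variable pl_term objects",
                                       class = "pl_bad_term")
  }
  constants
}

#' Ground specification rules over a constant set
#'
#' Enumerates every sort-respecting substitution of a rule's variables by
#' the supplied constants (injectively by default) and instantiates the
#' rule. Output order is deterministic: rules in input order, then
#' substitutions in lexicographic order of the constants assigned to the
#' variables (variables ordered by first appearance in the rule).
#'
#' @param rules A rules tibble as returned by [parse_rule_file()], with
#'   columns `id` and `formula`.
#' @param constants A list of [pl_const()] terms, or a data frame with
#'   columns `name` and `sort`.
#' @param injective Require distinct variables to take distinct constants.
#' @return A tibble with columns `rule_id`, `formula` (list of ground
#'   `pl_formula`) and `key` (serialized identity). Rules with no
#'   admissible substitution contribute no rows.
#' @export
ground_rules <- function(rules, constants, injective = TRUE) {
  constants <- as_constant_list(constants)
  by_sort <- list(
    protein = sort(vapply(Filter(function(t) t$sort == "protein", constants),
                          function(t) t$name, character(1))),
    ligand  = sort(vapply(Filter(function(t) t$sort == "ligand", constants),
                          function(t) t$name, character(1)))
  )
  out_id <- character(0); out_f <- list()
  for (i in seq_len(nrow(rules))) {
    f <- rules$formula[[i]]
    vars <- formula_vars(f)
    if (length(vars) == 0L) {
      out_id <- c(out_id, rules$id[[i]]); out_f <- c(out_f, list(f))
      next
    }
    cand <- lapply(vars, function(v) by_sort[[v$sort]])
    if (any(lengths(cand) == 0L)) next
    # odometer with the first variable slowest: lexicographic over tuples
    grid <- rev(expand.grid(rev(cand), stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE))
    for (r in seq_len(nrow(grid))) {
      names_r <- as.character(grid[r, ])
      if (injective && anyDuplicated(names_r)) next
      m <- Map(function(v, nm) pl_const(nm, v$sort), vars, names_r)
      names(m) <- vapply(vars, function(v) v$name, character(1))
      out_id <- c(out_id, rules$id[[i]])
      out_f <- c(out_f, list(subst_node(f, m)))
    }
  }
  tibble::tibble(rule_id = out_id, formula = out_f, key = fkeys(out_f))
}
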