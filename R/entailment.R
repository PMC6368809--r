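# Truth-table entailment: the independent semantic oracle against which the
# syntactic forward chainer is checked for soundness.

eval_formula_vec <- function(f, vals) {
  switch(f$type,
    atom = vals[[fkey(f)]],
    false = rep(FALSE, length(vals[[1]] %||% logical(0))) ,
    not = !eval_formula_vec(f$x, vals),
    and = eval_formula_vec(f$lhs, vals) & eval_formula_vec(f$rhs, vals),
    or  = eval_formula_vec(f$lhs, vals) | eval_formula_vec(f$rhs, vals),
    implies = !eval_formula_vec(f$lhs, vals) | eval_formula_vec(f$rhs, vals)
  )
}

#' Brute-force propositional entailment
#'
#' Decides whether the premises classically entail the goal(s) by
#' enumerating every truth assignment over the distinct ground atoms of
#' premises and goals (treating each ground atom as a propositional
#' variable; `False` is the always-false constant). True iff every
#' assignment satisfying all premises satisfies the goal. Exponential in
#' the atom count, hence the cap.
#'
#' @param premises List of ground `pl_formula`.
#' @param goal A ground `pl_formula`, or a list of them (each checked
#'   against the same premise set in one enumeration pass).
#' @param atom_cap Maximum number of distinct atoms allowed (default 16).
#' @return A logical scalar, or a logical vector when `goal` is a list.
#' @examples
#' p <- list(parse_formula("FD(A)"), parse_formula("FD(A) -> F(A)"))
#' entails_bruteforce(p, parse_formula("F(A)"))
#' @export
entails_bruteforce <- function(premises, goal, atom_cap = 16L) {
  if (is_pl_formula(premises)) premises <- list(premises)
  single <- is_pl_formula(goal)
  goals <- if (single) list(goal) else goal
  for (f in c(premises, goals)) {
    check_formula(f)
    if (!is_ground(f)) abort("entailment inputs must be ground", class = "pl_not_ground")
  }
  atoms <- list()
  akeys <- character(0)
  for (f in c(premises, goals)) {
    for (a in formula_atoms(f)) {
      k <- fkey(a)
      if (!k %in% akeys) { akeys <- c(akeys, k); atoms <- c(atoms, list(a)) }
    }
  }
  n <- length(akeys)
  if (n > atom_cap) {
    abort(sprintf("%d distinct atoms exceed the cap of %d", n, atom_cap),
          class = "pl_atom_cap")
  }
  nrows <- 2L^n
  vals <- stats::setNames(vector("list", n), akeys)
  for (i in seq_len(n)) {
    # bit i of the row number; row-major enumeration of all assignments
    vals[[i]] <- bitwAnd(seq_len(nrows) - 1L, bitwShiftL(1L, i - 1L)) > 0L
  }
  if (n == 0L) vals <- list(`__unit__` = logical(1))  # single empty assignment
  sat <- rep(TRUE, max(nrows, 1L))
  for (p in premises) sat <- sat & eval_formula_vec(p, vals)
  res <- vapply(goals, function(g) all(eval_formula_vec(g, vals)[sat]), logical(1))
  if (single) res[[1]] else res
}
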