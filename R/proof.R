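# Proof objects: ordered justified lines ending in a conclusion, in the
# Step/Reason layout of natural-deduction derivations. Lines are 1-based.

new_proof <- function(lines) {
  stopifnot(is.data.frame(lines))
  lines$index <- seq_len(nrow(lines))
  structure(tibble::as_tibble(lines), class = c("pl_proof", class(tibble::tibble())))
}

#' Build a proof from line descriptions
#'
#' Convenience constructor used to encode derivations line by line: each
#' line has a formula (DSL text), a justification kind (`given`,
#' `specification_rule`, or `inference_rule`), a rule name (a
#' specification-rule id such as `"R1"`, an inference-rule name such as
#' `"ModusPonens"`, or `"given"`), and for inference-rule lines the 1-based
#' indices of the antecedent lines.
#'
#' @param text Character vector of formula DSL strings, one per line.
#' @param kind Character vector of justification kinds.
#' @param rule Character vector of rule names.
#' @param antecedents List of integer vectors (empty for given /
#'   specification-rule lines).
#' @return A `pl_proof` tibble with columns `index`, `text`, `formula`,
#'   `kind`, `rule`, `antecedents`; the conclusion is the last line.
#' @export
proof_from_lines <- function(text, kind, rule, antecedents = NULL) {
  n <- length(text)
  antecedents <- antecedents %||% rep(list(integer(0)), n)
  antecedents <- lapply(antecedents, as.integer)
  formulas <- lapply(text, parse_formula)
  new_proof(tibble::tibble(
    text = vapply(formulas, serialize_formula, character(1)),
    formula = formulas, kind = kind, rule = rule, antecedents = antecedents
  ))
}

proof_conclusion <- function(proof) proof$formula[[nrow(proof)]]

#' @export
print.pl_proof <- function(x, ...) {
  cat(sprintf("<proof> %d line(s), conclusion: %s\n", nrow(x), x$text[[nrow(x)]]))
  for (i in seq_len(nrow(x))) {
    reason <- switch(x$kind[[i]],
      given = "Given premise",
      specification_rule = sprintf("Premise %s", x$rule[[i]]),
      inference_rule = sprintf("%s using step(s) %s", x$rule[[i]],
                               paste(x$antecedents[[i]], collapse = ", ")))
    cat(sprintf("  %2d. %-40s %s\n", i, x$text[[i]], reason))
  }
  invisible(x)
}

# Extract a linear proof of `formula` from a derivation by walking its
# recorded justifications. Support lines appear in a deterministic
# topological order (antecedents before conclusions, first-derived first).
#' @rdname forward_chain
#' @param deriv A `pl_derivation` from [forward_chain()].
#' @param formula A derived formula (or its key/text).
#' @export
derivation_proof <- function(deriv, formula) {
  stopifnot(inherits(deriv, "pl_derivation"))
  key <- if (is_pl_formula(formula)) fkey(formula) else formula
  if (is.null(deriv$justifications[[key]])) {
    abort(sprintf("formula not derived: %s", key), class = "pl_not_derived")
  }
  order <- character(0)
  visit <- function(k) {
    if (k %in% order) return(invisible(NULL))
    for (a in deriv$justifications[[k]]$antecedents) visit(a)
    order <<- c(order, k)
    invisible(NULL)
  }
  visit(key)
  idx <- stats::setNames(seq_along(order), order)
  lines <- tibble::tibble(
    text = vapply(order, function(k) serialize_formula(deriv$derived[[k]]), character(1)),
    formula = lapply(order, function(k) deriv$derived[[k]]),
    kind = vapply(order, function(k) deriv$justifications[[k]]$kind, character(1)),
    rule = vapply(order, function(k) deriv$justifications[[k]]$rule, character(1)),
    antecedents = lapply(order, function(k) {
      as.integer(unname(idx[deriv$justifications[[k]]$antecedents]))
    })
  )
  new_proof(lines)
}

#' Check a proof line by line
#'
#' Validates a natural-deduction derivation: a line is valid if it is (a) a
#' given premise, (b) a ground instance of the named specification rule
#' (matched up to commutativity of `&`/`|`, since rule variables are
#' universally quantified and those connectives are commutative), or (c)
#' the conclusion of the named inference rule applied to the formulas on
#' its antecedent lines (matched structurally, as the rule patterns are
#' directional). Antecedent indices must be 1-based and strictly smaller
#' than the line's own index. Invalid proofs are reported, not raised.
#'
#' @param proof A `pl_proof` (from [proof_from_lines()] or
#'   [derivation_proof()]).
#' @param given List of ground formulas admissible as given premises.
#' @param rules Specification rules tibble ([parse_rule_file()]); formulas
#'   may contain variables (groundable) or be ground.
#' @return A list: `valid` (flag), `first_invalid` (line index or `NA`),
#'   `line_ok` (logical per line).
#' @export
check_proof <- function(proof, given, rules) {
  stopifnot(inherits(proof, "pl_proof"), nrow(proof) >= 1L)
  if (is_pl_formula(given)) given <- list(given)
  given_keys <- fkeys(given)
  n <- nrow(proof)
  line_ok <- logical(n)
  for (i in seq_len(n)) {
    f <- proof$formula[[i]]
    line_ok[[i]] <- switch(proof$kind[[i]],
      given = fkey(f) %in% given_keys,
      specification_rule = {
        ids <- rules$id %||% rules$rule_id
        js <- which(ids == proof$rule[[i]])
        length(js) > 0L && any(vapply(js, function(j) {
          is_instance_of(f, rules$formula[[j]], commute = TRUE)
        }, logical(1)))
      },
      inference_rule = {
        ants <- proof$antecedents[[i]]
        ok <- length(ants) >= 1L && all(ants >= 1L) && all(ants < i) &&
          proof$rule[[i]] %in% inference_rule_names &&
          length(ants) == inference_rule_arity[[proof$rule[[i]]]]
        if (ok) {
          concs <- rule_conclusions(proof$rule[[i]], proof$formula[ants],
                                    universe = list(f))
          fkey(f) %in% fkeys(concs)
        } else FALSE
      },
      FALSE
    )
  }
  list(valid = all(line_ok),
       first_invalid = if (all(line_ok)) NA_integer_ else which(!line_ok)[1],
       line_ok = line_ok)
}

# ---- proof serialization (JSON lines) ---------------------------------------

#' Read and write proofs as JSON lines
#'
#' One JSON object per line: `{index, formula, kind, rule, antecedents}`,
#' with the formula in DSL text. Round-trips losslessly.
#'
#' @param proof A `pl_proof`.
#' @param path Destination / source file path.
#' @return `write_proof()` returns `proof` invisibly; `read_proof()` a
#'   `pl_proof`.
#' @export
write_proof <- function(proof, path) {
  lines <- vapply(seq_len(nrow(proof)), function(i) {
    jsonlite::toJSON(list(
      index = proof$index[[i]], formula = proof$text[[i]],
      kind = proof$kind[[i]], rule = proof$rule[[i]],
      antecedents = proof$antecedents[[i]]
    ), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(proof)
}

#' @rdname write_proof
#' @export
read_proof <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON)
  proof_from_lines(
    text = vapply(recs, `[[`, character(1), "formula"),
    kind = vapply(recs, `[[`, character(1), "kind"),
    rule = vapply(recs, `[[`, character(1), "rule"),
    antecedents = lapply(recs, function(r) as.integer(r$antecedents))
  )
}
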