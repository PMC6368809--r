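# Recursive-descent parser for the rule DSL.
#
# Grammar (ASCII spellings of the logic connectives):
#   formula := disj ('->' formula)?          right-associative
#   disj    := conj ('|' conj)*              left-associative
#   conj    := neg  ('&' neg)*               left-associative
#   neg     := '~' neg | primary
#   primary := '(' formula ')' | 'False' | PRED '(' term (',' term)* ')'
# Precedence: ~ > & > | > ->. Parentheses override.

pl_token_rx <- "->|[~&|(),:]|[A-Za-z_][A-Za-z0-9_]*|\\S"

tokenize_dsl <- function(text) {
  m <- gregexpr(pl_token_rx, text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(data.frame(tok = character(0), pos = integer(0)))
  data.frame(tok = regmatches(text, list(m))[[1]], pos = as.integer(m),
             stringsAsFactors = FALSE)
}

syntax_error <- function(msg, pos) {
  abort(sprintf("syntax error at position %d: %s", pos, msg),
        class = "pl_syntax_error", position = pos)
}

#' Parse a formula from DSL text
#'
#' Parses the ASCII rule notation: `~` negation, `&` conjunction, `|`
#' disjunction, `->` implication (right-associative), with precedence
#' `~` > `&` > `|` > `->` and parentheses overriding. `False` denotes the
#' always-false constant. Atom arguments are constants unless their name is
#' listed in `variables` (or `variables = "all"`, as in rule files where
#' every term is an implicitly quantified variable). Argument sorts come
#' from the predicate signature, never from the name; a name used with two
#' different sorts in one formula is an error.
#'
#' @param text A single DSL string, e.g. `"FD(Px) -> (ST(Px) -> F(Px))"`.
#' @param variables Character vector of names to read as variables, or
#'   `"all"`.
#' @return A `pl_formula`. Round-trips through [serialize_formula()].
#' @export
parse_formula <- function(text, variables = character()) {
  if (!is.character(text) || length(text) != 1L) {
    abort("text must be a single string", class = "pl_syntax_error")
  }
  toks <- tokenize_dsl(text)
  st <- new.env(parent = emptyenv())
  st$i <- 1L; st$toks <- toks; st$vars <- variables
  st$sorts <- new.env(parent = emptyenv())  # name -> sort consistency
  f <- p_formula(st)
  if (st$i <= nrow(st$toks)) {
    syntax_error(sprintf("unexpected '%s'", st$toks$tok[st$i]), st$toks$pos[st$i])
  }
  f
}

peek <- function(st) if (st$i <= nrow(st$toks)) st$toks$tok[st$i] else NA_character_
peek_pos <- function(st) if (st$i <= nrow(st$toks)) st$toks$pos[st$i] else nchar_end(st)
nchar_end <- function(st) if (nrow(st$toks)) st$toks$pos[nrow(st$toks)] + nchar(st$toks$tok[nrow(st$toks)]) else 1L
advance <- function(st) { st$i <- st$i + 1L; invisible(NULL) }
expect_tok <- function(st, tok) {
  if (!identical(peek(st), tok)) {
    syntax_error(sprintf("expected '%s', got '%s'", tok, peek(st) %||% "end of input"),
                 peek_pos(st))
  }
  advance(st)
}

p_formula <- function(st) {
  lhs <- p_disj(st)
  if (identical(peek(st), "->")) {
    advance(st)
    pl_implies(lhs, p_formula(st))  # right-associative
  } else lhs
}

p_disj <- function(st) {
  f <- p_conj(st)
  while (identical(peek(st), "|")) {
    advance(st)
    f <- pl_or(f, p_conj(st))
  }
  f
}

p_conj <- function(st) {
  f <- p_neg(st)
  while (identical(peek(st), "&")) {
    advance(st)
    f <- pl_and(f, p_neg(st))
  }
  f
}

p_neg <- function(st) {
  if (identical(peek(st), "~")) {
    advance(st)
    pl_not(p_neg(st))
  } else p_primary(st)
}

p_primary <- function(st) {
  tok <- peek(st)
  if (is.na(tok)) syntax_error("unexpected end of input", nchar_end(st))
  if (tok == "(") {
    advance(st)
    f <- p_formula(st)
    expect_tok(st, ")")
    return(f)
  }
  if (tok == "False") { advance(st); return(pl_false()) }
  if (grepl("^[A-Za-z_]", tok)) return(p_atom(st))
  syntax_error(sprintf("unexpected '%s'", tok), peek_pos(st))
}

p_atom <- function(st) {
  pred <- peek(st); pos <- peek_pos(st)
  advance(st)
  sig <- pl_signatures[[pred]]
  if (is.null(sig)) {
    abort(sprintf("unknown predicate '%s' at position %d", pred, pos),
          class = "pl_unknown_predicate", position = pos)
  }
  expect_tok(st, "(")
  args <- list()
  repeat {
    nm <- peek(st); npos <- peek_pos(st)
    if (is.na(nm) || !grepl("^[A-Za-z_]", nm)) {
      syntax_error("expected a term name", npos)
    }
    advance(st)
    slot <- length(args) + 1L
    if (slot > length(sig)) {
      abort(sprintf("%s takes %d argument(s); extra argument at position %d",
                    pred, length(sig), npos),
            class = "pl_bad_arity", position = npos)
    }
    sort <- sig[[slot]]
    prev <- get0(nm, envir = st$sorts, inherits = FALSE)
    if (!is.null(prev) && prev != sort) {
      abort(sprintf("term '%s' used with sorts %s and %s", nm, prev, sort),
            class = "pl_bad_sort", position = npos)
    }
    assign(nm, sort, envir = st$sorts)
    is_var <- identical(st$vars, "all") || nm %in% st$vars
    args[[slot]] <- new_term(nm, sort, var = is_var)
    if (identical(peek(st), ",")) { advance(st); next }
    break
  }
  if (length(args) != length(sig)) {
    abort(sprintf("%s takes %d argument(s), got %d", pred, length(sig), length(args)),
          class = "pl_bad_arity", position = pos)
  }
  expect_tok(st, ")")
  pl_atom(pred, args)
}

#' Parse a specification-rule file
#'
#' Rule files are UTF-8 text, one rule per non-comment line in the form
#' `ID: formula` (e.g. `R1: FD(Px) -> (ST(Px) -> F(Px))`); `#` starts a
#' comment and blank lines are ignored. Every term in a rule is a variable,
#' implicitly universally quantified. The package ships a transcription of
#' the thirteen sample specification rules at
#' `system.file("extdata", "rules_table1.plr", package = "protlogic")`.
#'
#' @param path Path to a rule file, or `text =` a character string.
#' @param text Rule text given directly instead of a file.
#' @return A tibble with columns `id`, `formula` (list of `pl_formula`
#'   with variables) and `text` (canonical serialization), in file order.
#' @export
parse_rule_file <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  } else {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  ids <- character(0); formulas <- list()
  for (ln in seq_along(lines)) {
    raw <- sub("#.*$", "", lines[[ln]])
    raw <- trimws(raw)
    if (!nzchar(raw)) next
    m <- regmatches(raw, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.+)$", raw))[[1]]
    if (length(m) != 3L) {
      abort(sprintf("line %d: expected 'ID: formula'", ln),
            class = "pl_syntax_error", line = ln)
    }
    id <- m[[2]]
    if (id %in% ids) {
      abort(sprintf("line %d: duplicate rule id '%s'", ln, id),
            class = "pl_duplicate_id", line = ln)
    }
    f <- tryCatch(parse_formula(m[[3]], variables = "all"),
                  error = function(e) {
                    abort(sprintf("line %d: %s", ln, conditionMessage(e)),
                          class = class(e)[1], line = ln, parent = e)
                  })
    ids <- c(ids, id)
    formulas <- c(formulas, list(f))
  }
  tibble::tibble(id = ids, formula = formulas,
                 text = vapply(formulas, serialize_formula, character(1)))
}

#' @rdname parse_rule_file
#' @export
spec_rules <- function() {
  parse_rule_file(system.file("extdata", "rules_table1.plr", package = "protlogic"))
}
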