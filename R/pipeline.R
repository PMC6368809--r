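# Orchestration: extraction -> given premises -> grounding -> forward
# chaining -> function transfer, yielding ranked prediction records.

#' Pipeline configuration
#'
#' Collects the tunable parameters of [annotate_protein()]:
#' `z_threshold` (collocation significance gate, default `-1.96`, the
#' stated operating point), `injective` (distinct rule variables take
#' distinct constants when grounding, default on), `max_iterations`
#' (forward-chaining cap, default 100), `min_support` (minimum count of
#' independent evidence items for a record to be reported, default 1),
#' `inference` (set `FALSE` for the explicit-only ablation that skips the
#' logic component entirely), and `seed` (default 17; recorded for
#' provenance — the pipeline itself is deterministic).
#'
#' @param z_threshold,injective,max_iterations,min_support,inference,seed
#'   See description.
#' @return A `pl_config` list.
#' @export
pipeline_config <- function(z_threshold = -1.96, injective = TRUE,
                            max_iterations = 100L, min_support = 1L,
                            inference = TRUE, seed = 17L) {
  stopifnot(max_iterations >= 1L, min_support >= 1L)
  structure(list(z_threshold = z_threshold, injective = injective,
                 max_iterations = as.integer(max_iterations),
                 min_support = as.integer(min_support),
                 inference = isTRUE(inference), seed = as.integer(seed)),
            class = "pl_config")
}

#' Deduplicate extracted premises into the inference inputs
#'
#' Turns extraction output into (a) the deduplicated ground given set for
#' the inference engine, with per-atom support counts (number of distinct
#' evidence sentences), and (b) the explicit prediction records for the
#' query protein from the functional-category payloads. `F(Px)` atoms for
#' *named* proteins are admitted as given premises (a function term
#' explicitly related to a named protein in text); explicit categories
#' concern the query protein itself and become predictions, not premises.
#'
#' @param premises A `pl_premises` from [extract_given_premises()].
#' @return A list with `given` (tibble `atom`, `formula`, `support`,
#'   `provenance`) and `explicit` (prediction-record tibble).
#' @export
mentions_to_given <- function(premises) {
  stopifnot(inherits(premises, "pl_premises"))
  atoms <- premises$atoms
  given <- dplyr::summarise(
    dplyr::group_by(atoms, .data$atom),
    formula = list(.data$formula[[1]]),
    support = dplyr::n_distinct(paste(.data$doc_id, .data$sentence_index)),
    provenance = paste(sort(unique(paste0(.data$doc_id, ":", .data$sentence_index))),
                       collapse = ";"),
    .groups = "drop")
  cats <- premises$categories
  explicit <- dplyr::summarise(
    dplyr::group_by(cats, .data$category),
    support = dplyr::n_distinct(paste(.data$doc_id, .data$sentence_index)),
    provenance = paste(sort(unique(paste0(.data$doc_id, ":", .data$sentence_index))),
                       collapse = ";"),
    .groups = "drop")
  explicit <- tibble::tibble(protein = rep(premises$protein, nrow(explicit)),
                             category = explicit$category,
                             evidence = rep("explicit", nrow(explicit)),
                             support = as.integer(explicit$support),
                             provenance = explicit$provenance)
  list(given = given, explicit = explicit)
}

#' Predict the functions of a protein from its literature
#'
#' The full pipeline for one unannotated protein: extract the biological
#' molecule terms semantically related to it (dictionary matching, pronoun
#' rule, Z-score, training index), assign the explicitly mentioned function
#' categories, then ground the specification rules over the extracted
#' constants and forward-chain to derive implicit `F(Px)` conclusions. Each
#' derived `F(Px)` transfers every category annotated to protein `Px` in
#' the annotation table, with the derivation recorded as a checkable proof.
#' Records below `min_support` are dropped; ordering is deterministic
#' (evidence type, support descending, category id).
#'
#' @param corpus Corpus tibble (`doc_id`, `protein_ids`, `text`).
#' @param protein_id The query protein id.
#' @param lexicon A lexicon ([read_lexicon()]).
#' @param rules Specification rules ([parse_rule_file()]); must be
#'   non-empty.
#' @param annotations Annotation tibble (`protein`, `category`).
#' @param index Optional training-corpus `pl_pair_index`.
#' @param config A [pipeline_config()].
#' @return A `pl_predictions` tibble (`protein`, `category`, `evidence`,
#'   `support`, `provenance`) with attributes `proofs` (named list of
#'   `pl_proof` for the derived `F` atoms) and `given` (the given-atom
#'   tibble).
#' @export
annotate_protein <- function(corpus, protein_id, lexicon, rules, annotations,
                             index = NULL, config = pipeline_config()) {
  if (is.null(rules) || nrow(rules) == 0L) {
    abort("empty specification rule set", class = "pl_no_rules")
  }
  premises <- extract_given_premises(corpus, protein_id, lexicon,
                                     index = index,
                                     z_threshold = config$z_threshold)
  parts <- mentions_to_given(premises)
  records <- parts$explicit
  proofs <- list()

  if (config$inference && nrow(parts$given) > 0L) {
    given <- parts$given$formula
    constants <- formula_constants(given)
    fa <- derive_function_atoms(given, rules, constants,
                                injective = config$injective,
                                max_iterations = config$max_iterations)
    if (nrow(fa) > 0L) {
      proofs <- stats::setNames(fa$proof, fa$atom)
      transfer <- dplyr::inner_join(
        tibble::tibble(source = fa$protein, atom = fa$atom),
        dplyr::rename(annotations, source = "protein"),
        by = "source", relationship = "many-to-many")
      if (nrow(transfer) > 0L) {
        implicit <- dplyr::summarise(
          dplyr::group_by(transfer, .data$category),
          support = dplyr::n_distinct(.data$source),
          provenance = paste(sort(unique(paste0("proof:", .data$atom, "<-",
                                                .data$source))), collapse = ";"),
          .groups = "drop")
        implicit <- tibble::tibble(protein = rep(protein_id, nrow(implicit)),
                                   category = implicit$category,
                                   evidence = rep("implicit", nrow(implicit)),
                                   support = as.integer(implicit$support),
                                   provenance = implicit$provenance)
        records <- dplyr::bind_rows(records, implicit)
      }
    }
  }

  records <- records[records$support >= config$min_support, ]
  records <- dplyr::arrange(records, .data$evidence, dplyr::desc(.data$support),
                            .data$category)
  structure(records, proofs = proofs, given = parts$given,
            class = c("pl_predictions", class(tibble::tibble())))
}

#' @export
print.pl_predictions <- function(x, ...) {
  cat(sprintf("<predictions> %d record(s) (%d explicit, %d implicit)\n",
              nrow(x), sum(x$evidence == "explicit"), sum(x$evidence == "implicit")))
  NextMethod()
}

#' Prediction proofs
#'
#' The checkable derivations behind a prediction table's implicit records.
#'
#' @param predictions A `pl_predictions` from [annotate_protein()].
#' @return Named list of `pl_proof` (by derived `F` atom).
#' @export
prediction_proofs <- function(predictions) attr(predictions, "proofs") %||% list()
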