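# Evaluation: per-protein recall / precision / F-value and the k-fold
# cross-validation harness.

#' Per-protein evaluation metrics
#'
#' With `C_p` the number of correctly predicted functions for protein `p`,
#' `N_p` its actual number of functions and `M_p` the number of predicted
#' functions: `recall = C_p / N_p`, `precision = C_p / M_p`, and
#' `f_value = 2 P R / (P + R)` (0 by convention when `P = R = 0`). All
#' vectorised; denominators must be positive.
#'
#' @param c_p,n_p,m_p Non-negative counts, `c_p <= min(n_p, m_p)`.
#' @param p,r Precision and recall values in `[0, 1]`.
#' @return Numeric values in `[0, 1]`.
#' @examples
#' recall(3, 4)
#' precision(3, 6)
#' f_value(0.5, 0.75)
#' @export
recall <- function(c_p, n_p) {
  check_counts(c_p, n_p)
  c_p / n_p
}

#' @rdname recall
#' @export
precision <- function(c_p, m_p) {
  check_counts(c_p, m_p)
  c_p / m_p
}

check_counts <- function(c_p, d) {
  if (any(d <= 0)) abort("denominator count must be positive: metric undefined",
                         class = "pl_undefined_metric")
  if (any(c_p < 0) || any(c_p > d)) {
    abort("need 0 <= correct count <= denominator", class = "pl_bad_arg")
  }
  invisible(NULL)
}

#' @rdname recall
#' @export
f_value <- function(p, r) {
  if (any(p < 0 | p > 1 | r < 0 | r > 1)) {
    abort("precision and recall must lie in [0, 1]", class = "pl_bad_arg")
  }
  ifelse(p + r == 0, 0, 2 * p * r / (p + r))
}

#' Score predictions against a gold annotation table
#'
#' Computes, per protein, the counts `C_p` (correct predictions: predicted
#' categories that are in the gold set), `N_p` (gold categories) and `M_p`
#' (predicted categories), plus recall, precision and F-value, then
#' macro-averages over the proteins with defined metrics. Proteins in the
#' gold table with no predictions (or, degenerately, no gold categories)
#' are skipped with a warning. Duplicate prediction rows are deduplicated
#' first, so the result is invariant to prediction order and multiplicity.
#'
#' @param predictions A predictions tibble (`protein`, `category`, ...);
#'   every predicted protein must appear in `gold`.
#' @param gold Annotation tibble (`protein`, `category`).
#' @return A `pl_eval` object; use [tidy()] for the per-protein table and
#'   [glance()] for the one-row macro summary.
#' @export
evaluate <- function(predictions, gold) {
  pred <- dplyr::distinct(tibble::as_tibble(predictions)[, c("protein", "category")])
  gold <- dplyr::distinct(tibble::as_tibble(gold)[, c("protein", "category")])
  missing <- setdiff(pred$protein, gold$protein)
  if (length(missing)) {
    abort(sprintf("predicted protein(s) missing from gold: %s",
                  paste(missing, collapse = ", ")), class = "pl_missing_gold")
  }
  proteins <- sort(unique(gold$protein))
  per <- lapply(proteins, function(p) {
    gset <- gold$category[gold$protein == p]
    pset <- pred$category[pred$protein == p]
    tibble::tibble(protein = p, c_p = length(intersect(pset, gset)),
                   n_p = length(gset), m_p = length(pset))
  })
  per <- dplyr::bind_rows(per)
  defined <- per$n_p > 0 & per$m_p > 0
  if (any(!defined)) {
    warn(sprintf("skipping %d protein(s) with undefined metrics (no predictions or no gold categories): %s",
                 sum(!defined), paste(per$protein[!defined], collapse = ", ")))
  }
  per$recall <- NA_real_; per$precision <- NA_real_; per$f_value <- NA_real_
  per$recall[defined] <- per$c_p[defined] / per$n_p[defined]
  per$precision[defined] <- per$c_p[defined] / per$m_p[defined]
  per$f_value[defined] <- f_value(per$precision[defined], per$recall[defined])
  structure(list(per_protein = per,
                 macro = tibble::tibble(
                   macro_recall = mean(per$recall[defined]),
                   macro_precision = mean(per$precision[defined]),
                   macro_f = mean(per$f_value[defined]),
                   n_proteins = sum(defined),
                   n_skipped = sum(!defined))),
            class = "pl_eval")
}

#' @export
print.pl_eval <- function(x, ...) {
  m <- x$macro
  cat(sprintf("<evaluation> %d protein(s) scored (%d skipped)\n  macro recall %.4f  precision %.4f  F %.4f\n",
              m$n_proteins, m$n_skipped, m$macro_recall, m$macro_precision, m$macro_f))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy evaluation results
#'
#' @param x A `pl_eval` from [evaluate()].
#' @param ... Unused.
#' @return `tidy()`: the per-protein count/metric tibble. `glance()`: the
#'   one-row macro-average tibble.
#' @export
tidy.pl_eval <- function(x, ...) x$per_protein

#' @rdname tidy.pl_eval
#' @export
glance.pl_eval <- function(x, ...) x$macro

#' Assign proteins to cross-validation folds
#'
#' Seeded shuffle followed by round-robin assignment, so folds differ in
#' size by at most one and the assignment is reproducible.
#'
#' @param protein_ids Character vector of protein ids.
#' @param k Number of folds (`2 <= k <= length(protein_ids)`).
#' @param seed Integer seed.
#' @return A tibble `protein`, `fold` (0-based fold index).
#' @export
kfold_split <- function(protein_ids, k = 5L, seed = 17L) {
  protein_ids <- unique(as.character(protein_ids))
  if (k < 2L) abort("k must be >= 2", class = "pl_bad_arg")
  if (k > length(protein_ids)) {
    abort("k exceeds the number of proteins", class = "pl_bad_arg")
  }
  shuffled <- withr::with_seed(seed, sample(protein_ids))
  tibble::tibble(protein = shuffled,
                 fold = (seq_along(shuffled) - 1L) %% as.integer(k))
}

#' k-fold cross-validation of the full pipeline
#'
#' For each fold: the training proteins' documents form the training corpus
#' (related-pair index) and the training annotations form the transfer
#' table; each held-out protein is re-annotated from its own documents and
#' scored against its gold annotations.
#'
#' @param corpus Corpus tibble.
#' @param lexicon A lexicon.
#' @param rules Specification rules.
#' @param annotations Gold annotation tibble (`protein`, `category`).
#' @param k,seed Fold count and shuffle seed ([kfold_split()]).
#' @param config A [pipeline_config()].
#' @return A tibble with one row per fold (`fold`, `n_test`,
#'   `macro_recall`, `macro_precision`, `macro_f`).
#' @export
cross_validate <- function(corpus, lexicon, rules, annotations, k = 5L,
                           seed = 17L, config = pipeline_config()) {
  folds <- kfold_split(unique(annotations$protein), k = k, seed = seed)
  out <- lapply(sort(unique(folds$fold)), function(fd) {
    test_p <- folds$protein[folds$fold == fd]
    train_p <- folds$protein[folds$fold != fd]
    train_docs <- corpus[vapply(corpus$protein_ids,
                                function(ids) any(ids %in% train_p), logical(1)), ]
    idx <- if (nrow(train_docs)) build_related_pair_index(train_docs, lexicon,
                                                          config$z_threshold)
           else NULL
    train_ann <- annotations[annotations$protein %in% train_p, ]
    preds <- lapply(test_p, function(p) {
      tryCatch(annotate_protein(corpus, p, lexicon, rules, train_ann,
                                index = idx, config = config),
               pl_protein_not_in_corpus = function(e) NULL)
    })
    preds <- dplyr::bind_rows(preds[!vapply(preds, is.null, logical(1))])
    if (nrow(preds) == 0L) {
      return(tibble::tibble(fold = fd, n_test = length(test_p),
                            macro_recall = NA_real_, macro_precision = NA_real_,
                            macro_f = NA_real_))
    }
    ev <- suppressWarnings(
      evaluate(preds, annotations[annotations$protein %in% test_p, ]))
    tibble::tibble(fold = fd, n_test = length(test_p),
                   macro_recall = ev$macro$macro_recall,
                   macro_precision = ev$macro$macro_precision,
                   macro_f = ev$macro$macro_f)
  })
  dplyr::bind_rows(out)
}
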