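# Plain-text interchange formats: JSONL corpora, TSV annotations and
# predictions.

#' Read and write a document corpus (JSON lines)
#'
#' One JSON object per line: `{"doc_id": ..., "protein_ids": [...],
#' "text": ...}`.
#'
#' @param path File path.
#' @param corpus A tibble with columns `doc_id`, `protein_ids`
#'   (list-column), `text`.
#' @return `read_corpus()` returns the corpus tibble.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON)
  tibble::tibble(
    doc_id = vapply(recs, function(r) as.character(r$doc_id), character(1)),
    protein_ids = lapply(recs, function(r) as.character(r$protein_ids)),
    text = vapply(recs, function(r) as.character(r$text), character(1))
  )
}

#' @rdname read_corpus
#' @export
write_corpus <- function(corpus, path) {
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    jsonlite::toJSON(list(doc_id = corpus$doc_id[[i]],
                          protein_ids = as.list(corpus$protein_ids[[i]]),
                          text = corpus$text[[i]]),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(corpus)
}

#' Read and write a protein annotation table
#'
#' A two-column TSV (`protein`, `category`) mapping already-annotated
#' proteins to their function categories — a minimal gene-association
#' subset.
#'
#' @param path File path.
#' @param annotations A tibble with columns `protein`, `category`.
#' @return `read_annotations()` returns the annotations tibble.
#' @export
read_annotations <- function(path) {
  tbl <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "")
  if (!all(c("protein", "category") %in% names(tbl))) {
    abort("annotations need columns protein, category", class = "pl_bad_annotations")
  }
  if (any(!nzchar(tbl$protein)) || any(!nzchar(tbl$category))) {
    abort("empty protein or category id", class = "pl_bad_annotations")
  }
  dplyr::distinct(tibble::as_tibble(tbl[, c("protein", "category")]))
}

#' @rdname read_annotations
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(as.data.frame(annotations[, c("protein", "category")]),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(annotations)
}

#' Read and write prediction records (TSV)
#'
#' Columns: `protein`, `category`, `evidence` (`explicit`/`implicit`),
#' `support` (integer count of independent evidence items), `provenance`.
#' The round trip through disk is lossless; malformed rows on read are
#' reported with their line number.
#'
#' @param records A predictions tibble (from [annotate_protein()]).
#' @param path File path.
#' @return `read_predictions()` returns the predictions tibble.
#' @export
write_predictions <- function(records, path) {
  cols <- c("protein", "category", "evidence", "support", "provenance")
  utils::write.table(as.data.frame(records)[, cols, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(records)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) abort("empty predictions file", class = "pl_bad_predictions")
  cols <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  need <- c("protein", "category", "evidence", "support", "provenance")
  if (!identical(cols, need)) {
    abort(sprintf("line 1: expected header %s", paste(need, collapse = "\t")),
          class = "pl_bad_predictions", line = 1L)
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  recs <- lapply(seq_along(body), function(i) {
    f <- strsplit(body[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) != 5L) {
      abort(sprintf("line %d: expected 5 fields, got %d", i + 1L, length(f)),
            class = "pl_bad_predictions", line = i + 1L)
    }
    sup <- suppressWarnings(as.integer(f[[4]]))
    if (is.na(sup)) {
      abort(sprintf("line %d: support '%s' is not an integer", i + 1L, f[[4]]),
            class = "pl_bad_predictions", line = i + 1L)
    }
    if (!f[[3]] %in% c("explicit", "implicit")) {
      abort(sprintf("line %d: bad evidence '%s'", i + 1L, f[[3]]),
            class = "pl_bad_predictions", line = i + 1L)
    }
    tibble::tibble(protein = f[[1]], category = f[[2]], evidence = f[[3]],
                   support = sup, provenance = f[[5]])
  })
  dplyr::bind_rows(c(list(tibble::tibble(protein = character(0),
                                         category = character(0),
                                         evidence = character(0),
                                         support = integer(0),
                                         provenance = character(0))), recs))
}
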