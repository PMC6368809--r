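# Seeded synthetic corpora with planted co-occurrence and relatedness
# structure. The generator stands in for a large literature training set:
# sentences are assembled from deliberately simple lexical templates
# (the extraction rules are lexical, so syntactic realism is a non-goal)
# with planted pairs appearing at controlled per-sentence rates.

#' Specify a synthetic corpus
#'
#' A corpus specification fixes everything the generator needs, so that a
#' corpus is fully determined by its seed: document count, sentences per
#' document, the lexicon whose entries populate sentences, planted term
#' pairs with per-sentence co-occurrence rates and a connector type
#' (`pronoun` sentences satisfy the relatedness rule, `disconnector`
#' sentences violate it, `none` co-occur without a connector), independent
#' background occurrence rates per entry, and optionally the specification
#' rules and an annotation table from which the intended ground truth
#' (atoms and function categories per protein) is derived.
#'
#' @param n_documents Number of documents.
#' @param sentences_per_document Length-2 integer range (inclusive).
#' @param lexicon A lexicon ([as_lexicon()]); planted pairs and background
#'   rates reference its `entry_id`s.
#' @param planted_pairs Tibble with columns `a`, `b` (entry ids), `rate`
#'   (per-sentence co-occurrence probability in `[0, 1]`), `connector`
#'   (`pronoun`/`disconnector`/`none`) and optionally `anchor` (a
#'   protein/ligand entry id attached to `b`'s phrase so template payloads
#'   bind to it).
#' @param background_rates Named numeric vector, entry id -> independent
#'   per-sentence occurrence probability.
#' @param rules,annotations Optional; when both are given the ground truth
#'   includes the function categories the planted atoms entail.
#' @param seed Integer seed (default 17).
#' @return A `pl_corpus_spec` list.
#' @export
corpus_spec <- function(n_documents, sentences_per_document = c(3L, 6L),
                        lexicon, planted_pairs = NULL, background_rates = NULL,
                        rules = NULL, annotations = NULL, seed = 17L) {
  if (nrow(lexicon) == 0L) abort("vocabulary is empty", class = "pl_bad_spec")
  planted_pairs <- planted_pairs %||%
    tibble::tibble(a = character(0), b = character(0), rate = double(0),
                   connector = character(0))
  if (!"anchor" %in% names(planted_pairs)) planted_pairs$anchor <- NA_character_
  ids <- lexicon$entry_id
  bad <- setdiff(c(planted_pairs$a, planted_pairs$b,
                   planted_pairs$anchor[!is.na(planted_pairs$anchor)],
                   names(background_rates)), ids)
  if (length(bad)) {
    abort(sprintf("spec references unknown lexicon entries: %s",
                  paste(bad, collapse = ", ")), class = "pl_bad_spec")
  }
  if (any(planted_pairs$rate < 0 | planted_pairs$rate > 1) ||
      any(background_rates < 0 | background_rates > 1)) {
    abort("rates must lie in [0, 1]", class = "pl_bad_spec")
  }
  if (!all(planted_pairs$connector %in% c("pronoun", "disconnector", "none"))) {
    abort("connector must be pronoun, disconnector or none", class = "pl_bad_spec")
  }
  structure(list(n_documents = as.integer(n_documents),
                 sentences_per_document = as.integer(sentences_per_document),
                 lexicon = lexicon, planted_pairs = planted_pairs,
                 background_rates = background_rates %||% numeric(0),
                 rules = rules, annotations = annotations,
                 seed = as.integer(seed)),
            class = "pl_corpus_spec")
}

entry_phrase <- function(lexicon, id) lexicon$patterns[[match(id, lexicon$entry_id)]][[1]]

#' Generate a synthetic corpus with planted structure
#'
#' Builds a document corpus from a [corpus_spec()]. Per sentence, each
#' planted pair fires independently with its rate and contributes a clause
#' from its connector template; each background entry appears independently
#' with its rate. Marginal and joint term frequencies therefore converge to
#' the specified rates as the corpus grows, and the output is byte-for-byte
#' reproducible from the seed.
#'
#' @param spec A `pl_corpus_spec`.
#' @return A list: `corpus` (tibble `doc_id`, `protein_ids`, `text`) and
#'   `truth` (list with `pairs` — the planted pairs with their intended
#'   relatedness labels —, `atoms` — intended given atoms per anchored
#'   template —, and `categories` — intended function categories, present
#'   when the spec carries rules and annotations).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "pl_corpus_spec"))
  lex <- spec$lexicon
  pp <- spec$planted_pairs
  br <- spec$background_rates
  protein_entries <- lex$entry_id[lex$payload_kind == "protein"]

  corpus <- withr::with_seed(spec$seed, {
    docs <- vector("list", spec$n_documents)
    rng <- spec$sentences_per_document
    for (d in seq_len(spec$n_documents)) {
      ns <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)
      sents <- character(ns)
      for (s in seq_len(ns)) {
        clauses <- character(0)
        if (nrow(pp)) {
          fire <- stats::runif(nrow(pp)) < pp$rate
          for (i in which(fire)) {
            a <- entry_phrase(lex, pp$a[[i]])
            b <- entry_phrase(lex, pp$b[[i]])
            anch <- pp$anchor[[i]]
            b_part <- if (!is.na(anch))
              paste("the", b, "of", entry_phrase(lex, anch)) else paste("the", b)
            clauses <- c(clauses, switch(pp$connector[[i]],
              pronoun = paste0(a, " , which involves ", b_part),
              disconnector = paste0(a, " was measured whereas ", b_part,
                                    " remained unchanged"),
              none = paste0(a, " and ", b_part, " were observed")))
          }
        }
        if (length(br)) {
          on <- stats::runif(length(br)) < br
          for (id in names(br)[on]) {
            clauses <- c(clauses, paste("the study recorded",
                                        entry_phrase(lex, id)))
          }
        }
        if (length(clauses) == 0L) clauses <- "no additional findings were reported"
        sents[[s]] <- paste0(paste(clauses, collapse = " ; "), ".")
      }
      # a document is associated with the protein entries it mentions
      txt <- paste(sents, collapse = " ")
      pids <- character(0)
      if (length(protein_entries)) {
        toks <- tokenize_text(txt)[[1]]
        pids <- lex$payload_value[lex$payload_kind == "protein" &
                                    vapply(lex$patterns, function(p)
                                      any(tolower(p) %in% toks), logical(1))]
      }
      docs[[d]] <- tibble::tibble(doc_id = sprintf("doc%04d", d),
                                  protein_ids = list(unique(pids)), text = txt)
    }
    dplyr::bind_rows(docs)
  })

  truth_pairs <- tibble::tibble(
    a = pmin(pp$a, pp$b), b = pmax(pp$a, pp$b),
    label = dplyr::case_when(pp$connector == "pronoun" ~ "related",
                             pp$connector == "disconnector" ~ "unrelated",
                             TRUE ~ "undetermined"),
    rate = pp$rate)
  anchored <- pp[!is.na(pp$anchor) & pp$connector == "pronoun" & pp$rate > 0, ]
  atoms <- tibble::tibble(protein = character(0), atom = character(0))
  if (nrow(anchored)) {
    rows <- lapply(seq_len(nrow(anchored)), function(i) {
      e <- match(anchored$b[[i]], lex$entry_id)
      if (lex$payload_kind[[e]] != "template") return(NULL)
      tm <- parse_template(lex$payload_value[[e]])
      if (length(tm$roles) != 1L) return(NULL)
      anch_val <- lex$payload_value[[match(anchored$anchor[[i]], lex$entry_id)]]
      tibble::tibble(protein = anch_val,
                     atom = sprintf("%s(%s)", tm$pred, anch_val))
    })
    atoms <- dplyr::bind_rows(rows[!vapply(rows, is.null, logical(1))])
  }
  truth <- list(pairs = truth_pairs, atoms = dplyr::distinct(atoms))
  if (!is.null(spec$rules) && !is.null(spec$annotations)) {
    cats <- lex$payload_value[lex$entry_id %in%
                                c(pp$b[pp$connector == "pronoun" & pp$rate > 0],
                                  pp$a[pp$connector == "pronoun" & pp$rate > 0]) &
                                lex$payload_kind == "category"]
    implied <- character(0)
    if (nrow(truth$atoms)) {
      given <- lapply(unique(truth$atoms$atom), parse_formula)
      fa <- derive_function_atoms(given, spec$rules)
      implied <- spec$annotations$category[spec$annotations$protein %in% fa$protein]
    }
    truth$categories <- sort(unique(c(cats, implied)))
  }
  list(corpus = corpus, truth = truth)
}

#' Lexicon and corpus spec used for Z-score calibration
#'
#' An all-background vocabulary of independent single-word terms: with no
#' planted pairs every term falls on the independence null, so the
#' collocation Z-scores should be approximately standard normal and about
#' 5% of pairs should exceed |z| = 1.96. Defaults: 64 terms at a 0.03
#' per-sentence rate over 20,000 single-sentence documents.
#'
#' @param n_terms Number of background terms.
#' @param rate Per-sentence occurrence probability of each term.
#' @param n_sentences Corpus size in sentences.
#' @param seed Integer seed.
#' @return A `pl_corpus_spec`.
#' @export
calibration_spec <- function(n_terms = 64L, rate = 0.03, n_sentences = 20000L,
                             seed = 17L) {
  lex <- tibble::tibble(
    entry_id = sprintf("T%03d", seq_len(n_terms)),
    patterns = as.list(sprintf("term%03d", seq_len(n_terms))),
    payload_kind = "category",
    payload_value = sprintf("GO:%07d", seq_len(n_terms))
  )
  corpus_spec(n_documents = n_sentences, sentences_per_document = c(1L, 1L),
              lexicon = lex,
              background_rates = stats::setNames(rep(rate, n_terms), lex$entry_id),
              seed = seed)
}

#' Demonstration fixtures: lexicon, rules, annotations and corpus spec
#'
#' A small self-contained study system used in examples and tests: a query
#' protein `PU1` whose literature relates it (pronoun-linked) to the
#' folding and structure of an annotated protein `PA`, to a function term
#' of `PB`'s non-covalent partner, and explicitly to an apoptosis category,
#' so that both explicit assignment and rule-based inference fire.
#'
#' @param seed Integer seed for the corpus spec.
#' @param n_documents Corpus size.
#' @return A list: `lexicon`, `rules`, `annotations`, `spec`
#'   (a `pl_corpus_spec`), `protein` (the query id `"PU1"`).
#' @export
demo_study <- function(seed = 17L, n_documents = 150L) {
  lexicon <- as_lexicon(tibble::tibble(
    entry_id = c("PU1", "PA", "PB", "FOLD", "STRUCT", "FUNC", "NCB", "APO"),
    pattern = c("PU1", "PA", "PB", "folding", "structure|conformation",
                "function|functional role", "non covalent binding",
                "apoptosis regulation"),
    payload_kind = c("protein", "protein", "protein", "template", "template",
                     "template", "template", "category"),
    payload_value = c("PU1", "PA", "PB", "FD(protein)", "ST(protein)",
                      "F(protein)", "NCBND(protein, protein)", "GO:0042981")
  ))
  rules <- spec_rules()
  annotations <- tibble::tibble(
    protein = c("PA", "PA", "PB"),
    category = c("GO:0006457", "GO:0051082", "GO:0005515")
  )
  planted <- tibble::tibble(
    a = c("PU1", "PU1", "PU1"),
    b = c("FOLD", "STRUCT", "APO"),
    rate = c(0.35, 0.35, 0.25),
    connector = "pronoun",
    anchor = c("PA", "PA", NA)
  )
  spec <- corpus_spec(
    n_documents = n_documents, sentences_per_document = c(2L, 4L),
    lexicon = lexicon, planted_pairs = planted,
    background_rates = c(FOLD = 0.02, STRUCT = 0.02, APO = 0.02),
    rules = rules, annotations = annotations, seed = seed
  )
  list(lexicon = lexicon, rules = rules, annotations = annotations,
       spec = spec, protein = "PU1")
}
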