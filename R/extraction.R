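# Statistical extraction of biological-molecule terms that co-occur
# explicitly with a protein in sentences: dictionary matching, the
# pronoun/disconnector sentence-level relatedness rules, and collocation
# Z-score significance against the independence null.

pl_pronouns <- c("that", "who", "which")
pl_disconnectors <- c("whereas", "but", "while")

pl_default_abbreviations <- c("e.g.", "i.e.", "etc.", "et al.", "cf.", "vs.",
                              "fig.", "figs.", "no.", "dr.")

# Lowercased word tokens, punctuation stripped; ':' is kept inside tokens so
# ontology identifiers such as GO:0006915 stay whole.
tokenize_text <- function(text) {
  m <- gregexpr("[a-z0-9]+(?::[a-z0-9]+)*", tolower(text), perl = TRUE)
  regmatches(tolower(text), m)
}

#' Segment a document into sentences
#'
#' Deterministic rule-based segmentation: split after `.`, `!` or `?`
#' followed by whitespace, except inside a configured abbreviation list
#' (e.g. "e.g.", "et al."). Tokens are lowercased word tokens with
#' punctuation stripped; spans over them are 0-based, half-open.
#'
#' @param text Document text (single string).
#' @param doc_id Document identifier carried through to the records.
#' @param abbreviations Character vector of abbreviations that must not end
#'   a sentence.
#' @return A tibble with columns `doc_id`, `sentence_index` (0-based),
#'   `text`, `tokens` (list of character vectors). Empty text gives zero
#'   rows.
#' @export
segment_sentences <- function(text, doc_id = "doc",
                              abbreviations = pl_default_abbreviations) {
  if (length(text) != 1L || is.na(text)) abort("text must be a single string",
                                               class = "pl_bad_arg")
  if (!nzchar(trimws(text))) {
    return(tibble::tibble(doc_id = character(0), sentence_index = integer(0),
                          text = character(0), tokens = list()))
  }
  protected <- text
  for (ab in abbreviations) {
    shield <- gsub(".", "\001", ab, fixed = TRUE)
    rx <- paste0("(?i)", gsub("([][.\\^$|(){}*+?\\\\])", "\\\\\\1", ab, perl = TRUE))
    protected <- gsub(rx, shield, protected, perl = TRUE)
  }
  parts <- strsplit(protected, "(?<=[.!?])\\s+", perl = TRUE)[[1]]
  parts <- gsub("\001", ".", parts, fixed = TRUE)
  parts <- parts[nzchar(trimws(parts))]
  tibble::tibble(
    doc_id = doc_id,
    sentence_index = seq_along(parts) - 1L,
    text = trimws(parts),
    tokens = tokenize_text(trimws(parts))
  )
}

corpus_sentences <- function(corpus, abbreviations = pl_default_abbreviations) {
  out <- purrr::map2(corpus$text, corpus$doc_id, segment_sentences,
                     abbreviations = abbreviations)
  s <- dplyr::bind_rows(c(list(segment_sentences("x")[0, ]), out))
  s$suid <- paste(s$doc_id, s$sentence_index, sep = "\r")
  s
}

# ---- lexicon ----------------------------------------------------------------

#' Read and validate a term lexicon
#'
#' The lexicon maps surface phrases to either a predicate template (the
#' phrase names a protein characteristic, e.g. `"folding"` carrying
#' `FD(protein)`, to be bound to a co-mentioned protein name), a functional
#' category (e.g. a GO identifier), or a protein/ligand name entry used for
#' dictionary named-entity lookup. TSV columns: `entry_id`, `pattern`
#' (`|`-separated surface alternatives), `payload_kind` (one of `template`,
#' `category`, `protein`, `ligand`) and `payload_value` (a template such as
#' `"FD(protein)"`, a category id, or the canonical constant name).
#'
#' @param path TSV file path.
#' @param tbl A data frame given directly (columns as above; `pattern` may
#'   already be a list of character vectors).
#' @return A validated lexicon tibble with columns `entry_id`, `patterns`
#'   (list), `payload_kind`, `payload_value`.
#' @export
read_lexicon <- function(path) {
  tbl <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "")
  as_lexicon(tbl)
}

#' @rdname read_lexicon
#' @export
as_lexicon <- function(tbl) {
  need <- c("entry_id", "payload_kind", "payload_value")
  if (!all(need %in% names(tbl))) {
    abort(sprintf("lexicon must have columns %s plus pattern/patterns",
                  paste(need, collapse = ", ")), class = "pl_bad_lexicon")
  }
  patterns <- if ("patterns" %in% names(tbl)) tbl$patterns else
    strsplit(tbl$pattern, "|", fixed = TRUE)
  patterns <- lapply(patterns, function(p) trimws(p[nzchar(trimws(p))]))
  if (any(lengths(patterns) == 0L)) {
    abort("every lexicon entry needs at least one surface pattern",
          class = "pl_bad_lexicon")
  }
  if (anyDuplicated(tbl$entry_id)) {
    abort("duplicate lexicon entry_id", class = "pl_bad_lexicon")
  }
  bad <- !tbl$payload_kind %in% c("template", "category", "protein", "ligand")
  if (any(bad)) {
    abort(sprintf("unknown payload_kind: %s",
                  paste(unique(tbl$payload_kind[bad]), collapse = ", ")),
          class = "pl_bad_lexicon")
  }
  for (i in which(tbl$payload_kind == "template")) parse_template(tbl$payload_value[[i]])
  tibble::tibble(entry_id = tbl$entry_id, patterns = patterns,
                 payload_kind = tbl$payload_kind, payload_value = tbl$payload_value)
}

# "FD(protein)" -> list(pred = "FD", roles = "protein"); validated against
# the predicate signatures.
parse_template <- function(value) {
  m <- regmatches(value, regexec("^([A-Za-z_]+)\\(([a-z, ]*)\\)$", value))[[1]]
  if (length(m) != 3L) abort(sprintf("malformed template '%s'", value),
                             class = "pl_bad_lexicon")
  pred <- m[[2]]
  roles <- trimws(strsplit(m[[3]], ",", fixed = TRUE)[[1]])
  sig <- pl_signatures[[pred]]
  if (is.null(sig)) abort(sprintf("template '%s': unknown predicate", value),
                          class = "pl_unknown_predicate")
  if (length(roles) != length(sig) || any(roles != sig)) {
    abort(sprintf("template '%s': expected roles (%s)", value,
                  paste(sig, collapse = ", ")), class = "pl_bad_lexicon")
  }
  list(pred = pred, roles = roles)
}

# ---- dictionary matching ----------------------------------------------------

# Case-insensitive, longest-match-first, non-overlapping matching of lexicon
# surface patterns over token sequences, for a whole sentence table at once.
match_terms_all <- function(sentences, lexicon) {
  empty <- tibble::tibble(doc_id = character(0), sentence_index = integer(0),
                          suid = character(0), entry_id = character(0),
                          start = integer(0), end = integer(0),
                          surface = character(0), payload_kind = character(0),
                          payload_value = character(0))
  if (nrow(sentences) == 0L) return(empty)
  pat <- tidyr::unnest(
    tibble::tibble(entry_id = lexicon$entry_id, pattern = lexicon$patterns),
    "pattern")
  pat$ptoks <- tokenize_text(pat$pattern)
  pat$len <- lengths(pat$ptoks)
  pat <- pat[pat$len > 0L, ]

  nt <- lengths(sentences$tokens)
  long <- tibble::tibble(
    suid = rep(sentences$suid, nt),
    row = rep(seq_len(nrow(sentences)), nt),
    pos = sequence(nt),                      # 1-based within sentence
    tok = unlist(sentences$tokens, use.names = FALSE)
  )
  cand <- list()
  # single-token patterns in one join
  p1 <- pat[pat$len == 1L, ]
  if (nrow(p1)) {
    p1$tok <- vapply(p1$ptoks, `[[`, character(1), 1L)
    hits <- dplyr::inner_join(long, p1[, c("tok", "entry_id")], by = "tok",
                              relationship = "many-to-many")
    if (nrow(hits)) {
      cand[[length(cand) + 1L]] <- tibble::tibble(
        suid = hits$suid, row = hits$row, entry_id = hits$entry_id,
        start = hits$pos - 1L, len = 1L)
    }
  }
  # multi-token patterns by shifted comparison
  for (i in which(pat$len > 1L)) {
    p <- pat$ptoks[[i]]; L <- length(p)
    n <- nrow(long)
    if (n < L) next
    ok <- long$tok[seq_len(n - L + 1L)] == p[[1]] &
      long$suid[seq_len(n - L + 1L)] == long$suid[seq_len(n - L + 1L) + L - 1L]
    for (j in 2:L) ok <- ok & long$tok[seq_len(n - L + 1L) + j - 1L] == p[[j]]
    idx <- which(ok)
    if (length(idx)) {
      cand[[length(cand) + 1L]] <- tibble::tibble(
        suid = long$suid[idx], row = long$row[idx], entry_id = pat$entry_id[[i]],
        start = long$pos[idx] - 1L, len = L)
    }
  }
  if (length(cand) == 0L) return(empty)
  cand <- dplyr::bind_rows(cand)
  cand$end <- cand$start + cand$len
  cand <- dplyr::arrange(cand, .data$suid, dplyr::desc(.data$len), .data$start,
                         .data$entry_id)
  # greedy non-overlap selection, longest first
  keep <- unlist(lapply(split(seq_len(nrow(cand)), cand$suid), function(rows) {
    taken_s <- integer(0); taken_e <- integer(0); sel <- integer(0)
    for (r in rows) {
      s <- cand$start[[r]]; e <- cand$end[[r]]
      if (!any(s < taken_e & e > taken_s)) {
        sel <- c(sel, r); taken_s <- c(taken_s, s); taken_e <- c(taken_e, e)
      }
    }
    sel
  }), use.names = FALSE)
  cand <- dplyr::arrange(cand[sort(keep), ], .data$suid, .data$start)
  toks <- sentences$tokens
  tibble::tibble(
    doc_id = sentences$doc_id[cand$row],
    sentence_index = sentences$sentence_index[cand$row],
    suid = cand$suid,
    entry_id = cand$entry_id,
    start = cand$start,
    end = cand$end,
    surface = mapply(function(r, s, e) paste(toks[[r]][(s + 1L):e], collapse = " "),
                     cand$row, cand$start, cand$end),
    payload_kind = lexicon$payload_kind[match(cand$entry_id, lexicon$entry_id)],
    payload_value = lexicon$payload_value[match(cand$entry_id, lexicon$entry_id)]
  )
}

#' Match lexicon terms in a sentence
#'
#' Case-insensitive dictionary matching of lexicon surface patterns against
#' the sentence tokens; longer patterns win over shorter ones and matches
#' never overlap. Template mentions are bound to the nearest protein/ligand
#' name mention in the sentence (token distance between spans, ties broken
#' leftward); binary predicates take the two nearest distinct names in
#' textual order. Mentions whose template cannot be bound carry `NA` atoms.
#'
#' @param sentence One row of [segment_sentences()] output (or a compatible
#'   list with `doc_id`, `sentence_index`, `tokens`).
#' @param lexicon A lexicon from [read_lexicon()]/[as_lexicon()].
#' @return A tibble of mentions: `doc_id`, `sentence_index`, `entry_id`,
#'   `start`, `end` (0-based half-open token span), `surface`,
#'   `payload_kind`, `payload_value`, `atom` (DSL text or `NA`), `formula`
#'   (list of `pl_formula` or `NULL`).
#' @export
match_terms <- function(sentence, lexicon) {
  s <- tibble::tibble(
    doc_id = sentence$doc_id[[1]] %||% "doc",
    sentence_index = sentence$sentence_index[[1]] %||% 0L,
    text = sentence$text[[1]] %||% NA_character_,
    tokens = list(if (is.list(sentence$tokens) && length(sentence$tokens) == 1L)
      sentence$tokens[[1]] else sentence$tokens)
  )
  s$suid <- paste(s$doc_id, s$sentence_index, sep = "\r")
  m <- match_terms_all(s, lexicon)
  bind_template_mentions(m)
}

# Distance between two disjoint half-open spans: tokens strictly separating
# them (0 when adjacent).
span_gap <- function(s1, e1, s2, e2) pmax(pmax(s1, s2) - pmin(e1, e2), 0L)

# Bind template mentions to the nearest name mentions, per sentence.
bind_template_mentions <- function(mentions) {
  mentions$atom <- NA_character_
  mentions$formula <- vector("list", nrow(mentions))
  tmpl_rows <- which(mentions$payload_kind == "template")
  if (length(tmpl_rows) == 0L) return(mentions)
  for (r in tmpl_rows) {
    here <- mentions$suid == mentions$suid[[r]]
    tm <- parse_template(mentions$payload_value[[r]])
    consts <- list()
    used <- character(0)
    ok <- TRUE
    for (role in tm$roles) {
      cand <- which(here & mentions$payload_kind == role &
                      !mentions$payload_value %in% used)
      if (length(cand) == 0L) { ok <- FALSE; break }
      d <- span_gap(mentions$start[[r]], mentions$end[[r]],
                    mentions$start[cand], mentions$end[cand])
      best <- cand[order(d, mentions$start[cand])][1]
      used <- c(used, mentions$payload_value[[best]])
      consts[[length(consts) + 1L]] <-
        list(name = mentions$payload_value[[best]], sort = role,
             start = mentions$start[[best]])
    }
    if (!ok) next
    if (length(consts) == 2L && tm$roles[[1]] == tm$roles[[2]]) {
      # two names of the same sort: textual order decides the argument order
      consts <- consts[order(vapply(consts, `[[`, integer(1), "start"))]
    }
    f <- pl_atom(tm$pred, lapply(consts, function(cn) pl_const(cn$name, cn$sort)))
    mentions$atom[[r]] <- serialize_formula(f)
    mentions$formula[[r]] <- f
  }
  mentions
}

# ---- relatedness ------------------------------------------------------------

#' Classify the relatedness of two mentions in a sentence
#'
#' Sentence-level linguistic rules: two mentions are `unrelated` if a
#' preposition-modifier disconnector (`whereas`, `but`, `while`) lies
#' strictly between their spans; otherwise `related` if a connecting
#' pronoun (`that`, `who`, `which`) lies strictly between; otherwise
#' `undetermined`. Symmetric in the two mentions.
#'
#' @param sentence A sentence record (needs `tokens`).
#' @param mention_a,mention_b Mention rows (need `start`, `end`; spans must
#'   be disjoint).
#' @return A one-row tibble: `label`, `connector` (matched word or `NA`),
#'   `connector_pos` (0-based token position or `NA`).
#' @export
classify_pair <- function(sentence, mention_a, mention_b) {
  toks <- if (is.list(sentence$tokens) && !is.character(sentence$tokens))
    sentence$tokens[[1]] else sentence$tokens
  s1 <- mention_a$start[[1]]; e1 <- mention_a$end[[1]]
  s2 <- mention_b$start[[1]]; e2 <- mention_b$end[[1]]
  if (s1 < e2 && s2 < e1) abort("mention spans overlap", class = "pl_overlap")
  lo <- min(e1, e2); hi <- max(s1, s2) - 1L   # 0-based strictly-between range
  between <- if (hi >= lo) toks[(lo + 1L):(hi + 1L)] else character(0)
  hit <- function(set) {
    w <- which(between %in% set)
    if (length(w)) list(word = between[[w[1]]], pos = lo + w[1] - 1L) else NULL
  }
  dis <- hit(pl_disconnectors)
  if (!is.null(dis)) {
    return(tibble::tibble(label = "unrelated", connector = dis$word,
                          connector_pos = dis$pos))
  }
  pro <- hit(pl_pronouns)
  if (!is.null(pro)) {
    return(tibble::tibble(label = "related", connector = pro$word,
                          connector_pos = pro$pos))
  }
  tibble::tibble(label = "undetermined", connector = NA_character_,
                 connector_pos = NA_integer_)
}

# Per-sentence relatedness for every co-occurring entry pair, vectorised
# over the whole corpus. Returns one row per (suid, a, b) with a < b and
# columns related / unrelated (any mention pair with that label).
pair_relatedness <- function(sentences, mentions) {
  out0 <- tibble::tibble(suid = character(0), a = character(0), b = character(0),
                         related = logical(0), unrelated = logical(0))
  if (nrow(mentions) < 2L) return(out0)
  m <- mentions[, c("suid", "entry_id", "start", "end")]
  pr <- dplyr::inner_join(m, m, by = "suid", suffix = c("_1", "_2"),
                          relationship = "many-to-many")
  pr <- pr[pr$entry_id_1 < pr$entry_id_2 |
             (pr$entry_id_1 == pr$entry_id_2 & pr$start_1 < pr$start_2), ]
  pr <- pr[pr$entry_id_1 != pr$entry_id_2, ]
  if (nrow(pr) == 0L) return(out0)
  pr$lo <- pmin(pr$end_1, pr$end_2)
  pr$hi <- pmax(pr$start_1, pr$start_2) - 1L
  nt <- lengths(sentences$tokens)
  long <- tibble::tibble(
    suid = rep(sentences$suid, nt),
    pos = sequence(nt) - 1L,
    tok = unlist(sentences$tokens, use.names = FALSE)
  )
  conn <- long[long$tok %in% c(pl_pronouns, pl_disconnectors), ]
  conn$is_dis <- conn$tok %in% pl_disconnectors
  pr$pair_row <- seq_len(nrow(pr))
  hits <- dplyr::inner_join(pr[, c("pair_row", "suid", "lo", "hi")], conn,
                            by = dplyr::join_by("suid", "lo" <= "pos", "hi" >= "pos"))
  agg <- dplyr::summarise(dplyr::group_by(hits, .data$pair_row),
                          any_dis = any(.data$is_dis),
                          any_pro = any(!.data$is_dis), .groups = "drop")
  pr$any_dis <- FALSE; pr$any_pro <- FALSE
  pr$any_dis[agg$pair_row] <- agg$any_dis
  pr$any_pro[agg$pair_row] <- agg$any_pro
  pr$label <- ifelse(pr$any_dis, "unrelated",
                     ifelse(pr$any_pro, "related", "undetermined"))
  dplyr::summarise(
    dplyr::group_by(pr, .data$suid, a = .data$entry_id_1, b = .data$entry_id_2),
    related = any(.data$label == "related"),
    unrelated = any(.data$label == "unrelated"),
    .groups = "drop")
}

# ---- Z-score ----------------------------------------------------------------

#' Collocation Z-score for a term pair
#'
#' Standardised deviation of the observed sentence co-occurrence count from
#' its expectation under independent placement: with `p = (n_a/N) *
#' (n_b/N)`, `z = (k - N p) / sqrt(N p (1 - p))`. Under the independence
#' null the statistic is asymptotically standard normal, so the
#' conventional 95% bounds (±1.96) apply.
#'
#' @param k Sentences containing both terms.
#' @param n_a,n_b Sentences containing each term.
#' @param N Total sentences in the corpus.
#' @return The Z-score (vectorised over the inputs).
#' @examples
#' compute_zscore(40, 50, 50, 1000)
#' @export
compute_zscore <- function(k, n_a, n_b, N) {
  if (any(N <= 0)) abort("N must be positive", class = "pl_bad_arg")
  if (any(n_a > N | n_b > N | k > pmin(n_a, n_b) | k < 0)) {
    abort("need 0 <= k <= min(n_a, n_b) <= N", class = "pl_bad_arg")
  }
  p <- (n_a / N) * (n_b / N)
  if (any(p == 0 | p == 1)) {
    abort("degenerate co-occurrence probability (p is 0 or 1): variance undefined",
          class = "pl_degenerate_p")
  }
  (k - N * p) / sqrt(N * p * (1 - p))
}

#' Sentence co-occurrence statistics for all term pairs
#'
#' Counts, for every unordered pair of lexicon entries observed in the
#' corpus, the marginal and joint sentence frequencies and the collocation
#' Z-score. Pairs whose variance is undefined (both terms in every
#' sentence) are flagged `degenerate` with `NA` z.
#'
#' @param sentences Output of [segment_sentences()] rows (internally
#'   `corpus_sentences()`), or a corpus tibble with `doc_id`,
#'   `protein_ids`, `text` columns.
#' @param lexicon A lexicon.
#' @return A tibble: `a`, `b` (entry ids, `a < b`), `k`, `n_a`, `n_b`, `N`,
#'   `z`, `degenerate`.
#' @export
cooccurrence_stats <- function(sentences, lexicon) {
  if (!"suid" %in% names(sentences)) sentences <- corpus_sentences(sentences)
  mentions <- match_terms_all(sentences, lexicon)
  N <- nrow(sentences)
  occ <- dplyr::distinct(mentions[, c("suid", "entry_id")])
  n_tbl <- dplyr::count(occ, .data$entry_id, name = "n")
  if (nrow(n_tbl) < 2L) {
    return(tibble::tibble(a = character(0), b = character(0), k = integer(0),
                          n_a = integer(0), n_b = integer(0), N = integer(0),
                          z = double(0), degenerate = logical(0)))
  }
  grid <- tidyr::crossing(a = n_tbl$entry_id, b = n_tbl$entry_id)
  grid <- grid[grid$a < grid$b, ]
  co <- dplyr::inner_join(occ, occ, by = "suid", suffix = c("_1", "_2"),
                          relationship = "many-to-many")
  co <- co[co$entry_id_1 < co$entry_id_2, ]
  k_tbl <- dplyr::count(co, a = .data$entry_id_1, b = .data$entry_id_2, name = "k")
  out <- dplyr::left_join(grid, k_tbl, by = c("a", "b"))
  out$k <- ifelse(is.na(out$k), 0L, out$k)
  out$n_a <- n_tbl$n[match(out$a, n_tbl$entry_id)]
  out$n_b <- n_tbl$n[match(out$b, n_tbl$entry_id)]
  out$N <- N
  p <- (out$n_a / N) * (out$n_b / N)
  out$degenerate <- p == 0 | p == 1
  out$z <- NA_real_
  idx <- !out$degenerate
  out$z[idx] <- (out$k[idx] - N * p[idx]) / sqrt(N * p[idx] * (1 - p[idx]))
  tibble::as_tibble(out)
}

# ---- training index ---------------------------------------------------------

#' Build the related-pair index from a training corpus
#'
#' Scans the training corpus and admits an unordered term pair into the
#' index iff (a) at least one sentence classifies the pair as related by
#' the pronoun rule, (b) sentences where a disconnector intervenes are
#' discarded as evidence (they do not veto other sentences), and (c) the
#' pair's collocation Z-score exceeds `z_threshold`. Pairs whose Z-score
#' variance is degenerate because both terms occur in every sentence are
#' treated as passing the significance test (their co-occurrence is
#' certain).
#'
#' @param corpus A corpus tibble (`doc_id`, `protein_ids` list-column,
#'   `text`), e.g. from [read_corpus()].
#' @param lexicon A lexicon.
#' @param z_threshold Significance threshold on the Z-score (default
#'   `-1.96`, the literal stated operating point; see the methods vignette
#'   for the discussion of the one-sided `+1.96` alternative).
#' @return A `pl_pair_index`: tibble of accepted pairs (`a`, `b`, `k`,
#'   `n_a`, `n_b`, `z`, `n_related`) with attributes `N` and `z_threshold`.
#' @export
build_related_pair_index <- function(corpus, lexicon, z_threshold = -1.96) {
  sentences <- corpus_sentences(corpus)
  stats <- cooccurrence_stats(sentences, lexicon)
  mentions <- match_terms_all(sentences, lexicon)
  rel <- pair_relatedness(sentences, mentions)
  nrel <- dplyr::count(rel[rel$related, ], .data$a, .data$b, name = "n_related")
  out <- dplyr::inner_join(stats, nrel, by = c("a", "b"))
  out <- out[out$degenerate | (!is.na(out$z) & out$z > z_threshold), ]
  out <- dplyr::arrange(out[, c("a", "b", "k", "n_a", "n_b", "z", "n_related")],
                        .data$a, .data$b)
  structure(tibble::as_tibble(out), N = nrow(sentences), z_threshold = z_threshold,
            class = c("pl_pair_index", class(tibble::tibble())))
}

#' @rdname build_related_pair_index
#' @param index A `pl_pair_index`.
#' @param a,b Entry ids (order-free).
#' @export
has_pair <- function(index, a, b) {
  lo <- pmin(a, b); hi <- pmax(a, b)
  any(index$a == lo & index$b == hi)
}

#' @export
print.pl_pair_index <- function(x, ...) {
  cat(sprintf("<related-pair index> %d accepted pair(s) from %d sentences (z > %.3g)\n",
              nrow(x), attr(x, "N"), attr(x, "z_threshold")))
  NextMethod()
}

#' Write / read a related-pair index as TSV
#'
#' @param index A `pl_pair_index`.
#' @param path File path.
#' @export
write_pair_index <- function(index, path) {
  hdr <- sprintf("# N=%d z_threshold=%.10g", attr(index, "N"), attr(index, "z_threshold"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(index), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(index)
}

#' @rdname write_pair_index
#' @export
read_pair_index <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[[1]]
  N <- as.integer(sub(".*N=(\\d+).*", "\\1", hdr))
  zt <- as.numeric(sub(".*z_threshold=([-0-9.e+]+).*", "\\1", hdr))
  tbl <- utils::read.delim(text = paste(lines[-1], collapse = "\n"), sep = "\t",
                           stringsAsFactors = FALSE)
  structure(tibble::as_tibble(tbl), N = N, z_threshold = zt,
            class = c("pl_pair_index", class(tibble::tibble())))
}

# ---- given-premise extraction -----------------------------------------------

#' Extract explicit categories and given premises for a protein
#'
#' For every document associated with the query protein, finds lexicon
#' terms semantically related to a mention of the protein: the pair must be
#' classified related in at least one sentence (pronoun rule, no
#' intervening disconnector), its query-corpus Z-score must exceed the
#' threshold, and — when a training index is supplied — the pair must also
#' be related in the training corpus. Related terms with a
#' functional-category payload become explicit function assignments; terms
#' with a predicate-template payload become ground given atoms bound to the
#' nearest named protein/ligand in the evidence sentence. Provenance (doc,
#' sentence) is retained throughout, and every constant in an emitted atom
#' is mentioned in the cited sentence.
#'
#' @param corpus Corpus tibble (`doc_id`, `protein_ids`, `text`).
#' @param protein_id The query protein; must have a `protein` lexicon entry
#'   and be associated with at least one document.
#' @param lexicon A lexicon.
#' @param index Optional `pl_pair_index` from the training corpus.
#' @param z_threshold Z-score threshold applied in the query corpus.
#' @return A `pl_premises` list: `protein`, `categories` (tibble
#'   `category`, `doc_id`, `sentence_index`), `atoms` (tibble `atom`,
#'   `formula` list, `doc_id`, `sentence_index`). Document order does not
#'   affect the result (rows are sorted).
#' @export
extract_given_premises <- function(corpus, protein_id, lexicon, index = NULL,
                                   z_threshold = -1.96) {
  pu_entries <- lexicon$entry_id[lexicon$payload_kind == "protein" &
                                   lexicon$payload_value == protein_id]
  if (length(pu_entries) == 0L) {
    abort(sprintf("protein '%s' has no lexicon entry", protein_id),
          class = "pl_unknown_protein")
  }
  pu <- pu_entries[[1]]
  assoc <- vapply(corpus$protein_ids, function(ids) protein_id %in% ids, logical(1))
  if (!any(assoc)) {
    abort(sprintf("protein '%s' is not associated with any document", protein_id),
          class = "pl_protein_not_in_corpus")
  }
  corpus <- corpus[assoc, ]
  sentences <- corpus_sentences(corpus)
  mentions <- bind_template_mentions(match_terms_all(sentences, lexicon))
  stats <- cooccurrence_stats(sentences, lexicon)
  rel <- pair_relatedness(sentences, mentions)

  empty <- list(
    protein = protein_id,
    categories = tibble::tibble(category = character(0), doc_id = character(0),
                                sentence_index = integer(0)),
    atoms = tibble::tibble(atom = character(0), formula = list(),
                           doc_id = character(0), sentence_index = integer(0))
  )
  class(empty) <- "pl_premises"
  if (nrow(rel) == 0L) return(empty)

  # entries whose pair with the query protein passes all three gates
  rel_pu <- rel[(rel$a == pu | rel$b == pu) & rel$related, ]
  if (nrow(rel_pu) == 0L) return(empty)
  rel_pu$other <- ifelse(rel_pu$a == pu, rel_pu$b, rel_pu$a)
  z_ok <- function(e) {
    lo <- pmin(pu, e); hi <- pmax(pu, e)
    row <- stats[stats$a == lo & stats$b == hi, ]
    nrow(row) == 1L && (row$degenerate || (!is.na(row$z) && row$z > z_threshold))
  }
  idx_ok <- function(e) is.null(index) || has_pair(index, pu, e)
  keep_entry <- vapply(unique(rel_pu$other),
                       function(e) z_ok(e) && idx_ok(e), logical(1))
  accepted <- unique(rel_pu$other)[keep_entry]
  ev <- rel_pu[rel_pu$other %in% accepted, c("suid", "other")]
  if (nrow(ev) == 0L) return(empty)

  ev_m <- dplyr::inner_join(mentions, ev, by = c("suid" = "suid",
                                                 "entry_id" = "other"),
                            relationship = "many-to-many")
  cats <- ev_m[ev_m$payload_kind == "category", ]
  atoms <- ev_m[ev_m$payload_kind == "template" & !is.na(ev_m$atom), ]
  out <- list(
    protein = protein_id,
    categories = dplyr::arrange(dplyr::distinct(
      tibble::tibble(category = cats$payload_value, doc_id = cats$doc_id,
                     sentence_index = cats$sentence_index)),
      .data$category, .data$doc_id, .data$sentence_index),
    atoms = dplyr::arrange(dplyr::distinct(
      tibble::tibble(atom = atoms$atom, formula = atoms$formula,
                     doc_id = atoms$doc_id, sentence_index = atoms$sentence_index),
      .data$atom, .data$doc_id, .data$sentence_index, .keep_all = TRUE),
      .data$atom, .data$doc_id, .data$sentence_index)
  )
  class(out) <- "pl_premises"
  out
}

#' @export
print.pl_premises <- function(x, ...) {
  cat(sprintf("<premises for %s> %d explicit category record(s), %d given atom record(s)\n",
              x$protein, nrow(x$categories), nrow(x$atoms)))
  if (nrow(x$atoms)) cat("  atoms:", paste(unique(x$atoms$atom), collapse = ", "), "\n")
  if (nrow(x$categories)) cat("  categories:",
                              paste(unique(x$categories$category), collapse = ", "), "\n")
  invisible(x)
}
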