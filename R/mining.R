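#' Dictionary matching policy
#'
#' Matching is effectively case-insensitive (both text and lexicon are
#' uppercased), word-boundary aware (the characters flanking a hit must be
#' non-alphanumeric or the string edge, so hyphenated contexts like
#' "BDNF-dependent" still yield a BDNF hit), and resolved leftmost-longest:
#' scanning left to right, the longest candidate starting at the earliest
#' unconsumed position wins and overlapping candidates are discarded.
#'
#' @param leftmost_longest must currently be `TRUE`; reserved for
#'   alternative resolution schemes.
#' @return a `match_policy` list.
#' @export
match_policy <- function(leftmost_longest = TRUE) {
  stopifnot(isTRUE(leftmost_longest))
  structure(list(leftmost_longest = TRUE), class = "match_policy")
}

#' Find gene/protein mentions in one text
#'
#' Returns every lexicon hit in `text` as a data.frame of mention hits with
#' 0-based, half-open character offsets. `surface` is the exact text slice
#' `[start, end)`. Hits are non-overlapping, boundary-checked, sorted by
#' `start`, and never come from blocklisted surfaces.
#'
#' @param text a character scalar (typically an abstract body).
#' @param lexicon a [gene_lexicon()].
#' @param policy a [match_policy()].
#' @param record_id optional id copied into the result.
#' @return data.frame with columns `record_id`, `symbol`, `start`, `end`,
#'   `surface`.
#' @export
match_mentions <- function(text, lexicon, policy = match_policy(),
                           record_id = NA_character_) {
  empty <- data.frame(record_id = character(), symbol = character(),
                      start = integer(), end = integer(),
                      surface = character(), stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)
  upper <- toupper(text)
  surfaces <- names(lexicon$surface_map)
  cand_start <- integer(); cand_len <- integer(); cand_sym <- character()
  for (i in seq_along(surfaces)) {
    s <- surfaces[i]
    m <- gregexpr(s, upper, fixed = TRUE)[[1]]
    if (m[1] == -1L) next
    len <- nchar(s)
    for (pos in as.integer(m)) {
      before <- if (pos > 1L) substr(upper, pos - 1L, pos - 1L) else ""
      after_i <- pos + len
      after <- if (after_i <= nchar(upper)) substr(upper, after_i, after_i) else ""
      if (!grepl("[0-9A-Za-z]", before) && !grepl("[0-9A-Za-z]", after)) {
        cand_start <- c(cand_start, pos)
        cand_len <- c(cand_len, len)
        cand_sym <- c(cand_sym, lexicon$surface_map[[i]])
      }
    }
  }
  if (!length(cand_start)) return(empty)
  ord <- order(cand_start, -cand_len, cand_sym)
  cand_start <- cand_start[ord]; cand_len <- cand_len[ord]
  cand_sym <- cand_sym[ord]
  keep <- logical(length(cand_start)); consumed_to <- 0L
  for (i in seq_along(cand_start)) {
    if (cand_start[i] > consumed_to) {
      keep[i] <- TRUE
      consumed_to <- cand_start[i] + cand_len[i] - 1L
    }
  }
  st0 <- cand_start[keep] - 1L                   # 0-based, half-open
  en0 <- st0 + cand_len[keep]
  data.frame(
    record_id = record_id, symbol = cand_sym[keep],
    start = st0, end = en0,
    surface = substring(text, st0 + 1L, en0),
    stringsAsFactors = FALSE
  )
}

#' Mine every abstract of a corpus for lexicon mentions
#'
#' @param corpus an [abstract_corpus()].
#' @param lexicon a [gene_lexicon()].
#' @param fields which record fields are searched; offsets refer to the
#'   fields pasted with a single separating space.
#' @inheritParams match_mentions
#' @return one data.frame of mention hits (see [match_mentions()]).
#' @export
mine_corpus <- function(corpus, lexicon, policy = match_policy(),
                        fields = c("title", "body")) {
  fields <- match.arg(fields, c("title", "body"), several.ok = TRUE)
  hits <- lapply(seq_len(nrow(corpus)), function(i) {
    text <- paste(unlist(corpus[i, fields]), collapse = " ")
    match_mentions(text, lexicon, policy, record_id = corpus$record_id[i])
  })
  out <- do.call(rbind, c(hits, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- match_mentions("", lexicon)           # typed empty frame
  out
}

#' Identify records mentioning any disease term
#'
#' Boundary-aware, case-insensitive matching of multi-word disease terms,
#' using the same matcher as gene mentions (short terms are whitelisted
#' rather than length-filtered).
#'
#' @param corpus an [abstract_corpus()].
#' @param disease_terms character vector, e.g.
#'   `c("T2DM", "type 2 diabetes")`.
#' @inheritParams mine_corpus
#' @return character vector of `record_id`s with at least one disease hit.
#' @export
find_disease_records <- function(corpus, disease_terms,
                                 fields = c("title", "body")) {
  stopifnot(length(disease_terms) > 0)
  disease_terms <- unique(toupper(disease_terms))
  lex <- gene_lexicon(disease_terms[1], list(disease_terms[-1]),
                      whitelist = disease_terms, min_nchar = 1L)
  hits <- mine_corpus(corpus, lex, fields = fields)
  unique(hits$record_id)
}

#' Per-document symbol/disease co-occurrence counts
#'
#' Counts are per document: an abstract contributes at most 1 to any count
#' no matter how often a symbol is repeated inside it.
#'
#' @param hits either a mention-hit data.frame from [mine_corpus()] (only
#'   `record_id` and `symbol` are used) or a named list mapping record id
#'   to a character vector of symbols.
#' @param disease_records character vector of record ids containing at
#'   least one disease term (see [find_disease_records()]), or a named list
#'   in the same shape as `hits` whose names are used.
#' @param n_docs total number of curated abstracts N.
#' @return an object of class `cooccurrence_counts`: list with `n_docs`,
#'   `doc_count` (named integer n_x per symbol), `disease_doc_count`
#'   (n_d), `joint_count` (named integer n_xd per symbol).
#' @export
count_cooccurrence <- function(hits, disease_records, n_docs) {
  if (n_docs < 1L) stop("empty corpus")
  if (is.data.frame(hits)) {
    by_rec <- split(hits$symbol, hits$record_id)
  } else by_rec <- hits
  if (is.list(disease_records)) disease_records <- names(disease_records)
  disease_records <- unique(as.character(disease_records))

  per_doc <- lapply(by_rec, unique)
  symbols <- sort(unique(unlist(per_doc, use.names = FALSE)))
  doc_count <- vapply(symbols, function(s)
    sum(vapply(per_doc, function(v) s %in% v, logical(1))), integer(1))
  in_disease <- names(per_doc) %in% disease_records
  joint <- vapply(symbols, function(s)
    sum(vapply(per_doc[in_disease], function(v) s %in% v, logical(1))),
    integer(1))
  structure(
    list(n_docs = as.integer(n_docs),
         doc_count = doc_count,
         disease_doc_count = length(disease_records),
         joint_count = joint),
    class = "cooccurrence_counts"
  )
}

#' Pointwise mutual information of a symbol with the disease term set
#'
#' Document-level PMI in log base 2:
#' \deqn{\mathrm{pmi} = \log_2 \frac{n_{xd} \, N}{n_x \, n_d}}
#' where \eqn{N} is the corpus size, \eqn{n_x} the number of documents
#' mentioning the symbol, \eqn{n_d} the number of disease documents and
#' \eqn{n_{xd}} their joint count. PMI is 0 exactly at independence
#' (\eqn{n_{xd} N = n_x n_d}). A zero joint count yields the `-Inf`
#' sentinel by default; `correction = TRUE` substitutes
#' \eqn{n_{xd} + 0.5} in the numerator for zero joints only, so observed
#' co-occurrence is never perturbed.
#'
#' @param counts a [count_cooccurrence()] result.
#' @param symbol canonical symbol, must be present in `counts$doc_count`.
#' @param correction apply the add-0.5 continuity correction at
#'   \eqn{n_{xd} = 0}.
#' @return one-row data.frame: `symbol`, `pmi`, `n_x`, `n_xd`.
#' @export
compute_pmi <- function(counts, symbol, correction = FALSE) {
  if (!symbol %in% names(counts$doc_count))
    stop("unknown symbol: ", symbol)
  n_x <- counts$doc_count[[symbol]]
  if (n_x == 0L) stop("symbol has zero document count: ", symbol)
  n_d <- counts$disease_doc_count
  if (n_d < 1L) stop("no disease documents in corpus")
  n_xd <- counts$joint_count[[symbol]]
  num <- if (n_xd == 0L && correction) 0.5 else as.numeric(n_xd)
  pmi <- if (num == 0) -Inf else
    log2((num * counts$n_docs) / (as.numeric(n_x) * n_d))
  data.frame(symbol = symbol, pmi = pmi, n_x = n_x, n_xd = n_xd,
             stringsAsFactors = FALSE)
}

#' PMI scores for every counted symbol
#'
#' @inheritParams compute_pmi
#' @return data.frame with one row per symbol (`symbol`, `pmi`, `n_x`,
#'   `n_xd`), plus attribute `n_docs`.
#' @export
pmi_scores <- function(counts, correction = FALSE) {
  rows <- lapply(names(counts$doc_count), compute_pmi, counts = counts,
                 correction = correction)
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(symbol = character(), pmi = numeric(),
                      n_x = integer(), n_xd = integer(),
                      stringsAsFactors = FALSE)
  attr(out, "n_docs") <- counts$n_docs
  out
}

#' Rank disease-associated proteins by PMI
#'
#' Filters scored symbols by support and PMI thresholds and returns unique
#' symbols sorted by PMI descending, ties broken alphabetically. Symbols
#' with non-finite PMI (zero joint count sentinel) are excluded unless
#' `include_zero_joint = TRUE`.
#'
#' @param scores a [pmi_scores()] data.frame.
#' @param min_pmi minimum PMI retained.
#' @param min_docs minimum supporting document count `n_x`.
#' @param include_zero_joint retain `-Inf` sentinel rows (they sort last).
#' @return character vector of symbols, ranked.
#' @export
rank_proteins <- function(scores, min_pmi = -Inf, min_docs = 1L,
                          include_zero_joint = FALSE) {
  keep <- scores$n_x >= min_docs & scores$pmi >= min_pmi
  if (!include_zero_joint) keep <- keep & is.finite(scores$pmi)
  s <- scores[keep, , drop = FALSE]
  s <- s[!duplicated(s$symbol), , drop = FALSE]
  s$symbol[order(-s$pmi, s$symbol)]
}

#' Write PMI scores as TSV
#'
#' Columns: `symbol`, `pmi`, `n_x`, `n_xd`, `n_docs`.
#'
#' @param scores a [pmi_scores()] data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pmi_scores <- function(scores, path) {
  out <- scores
  out$n_docs <- attr(scores, "n_docs")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
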