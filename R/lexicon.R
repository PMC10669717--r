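#' Build and validate a gene/protein lexicon
#'
#' The lexicon maps canonical gene symbols (stored uppercase) to synonym
#' sets used for dictionary matching. Two safety rails guard against the
#' classic failure modes of symbol matching in free text:
#'
#' * a surface form assigned to two canonical symbols is ambiguous; it is
#'   either rejected (`collision = "error"`) or routed to the blocklist
#'   (`collision = "blocklist"`, the default) so it can never emit a hit;
#' * surfaces shorter than `min_nchar` characters (pervasive false
#'   positives in abstracts: "OR", "IT", ...) are auto-blocklisted unless
#'   explicitly whitelisted.
#'
#' @param symbols character vector of canonical symbols.
#' @param synonyms list (parallel to `symbols`) of character vectors of
#'   synonyms; `NULL` for none.
#' @param blocked character vector of surface forms never to match.
#' @param whitelist character vector of short surfaces to keep despite
#'   `min_nchar`.
#' @param min_nchar minimum surface length matched without whitelisting.
#' @param collision what to do with a synonym claimed by two symbols.
#' @return an object of class `gene_lexicon` with elements `entries`
#'   (named list symbol -> surface set), `blocklist`, and `surface_map`
#'   (named character vector surface -> canonical symbol).
#' @export
gene_lexicon <- function(symbols, synonyms = NULL, blocked = character(),
                         whitelist = character(), min_nchar = 3L,
                         collision = c("blocklist", "error")) {
  collision <- match.arg(collision)
  symbols <- toupper(trimws(symbols))
  if (anyDuplicated(symbols))
    stop("duplicate canonical symbols: ",
         paste(unique(symbols[duplicated(symbols)]), collapse = ", "))
  if (is.null(synonyms)) synonyms <- vector("list", length(symbols))
  stopifnot(length(synonyms) == length(symbols))
  whitelist <- toupper(whitelist)
  blocked <- toupper(blocked)
  if (length(bad <- intersect(blocked, whitelist)))
    stop("blocklist and whitelist overlap: ", paste(bad, collapse = ", "))

  entries <- stats::setNames(vector("list", length(symbols)), symbols)
  for (i in seq_along(symbols))
    entries[[i]] <- unique(c(symbols[i], toupper(trimws(synonyms[[i]]))))

  surf <- unlist(entries, use.names = FALSE)
  owner <- rep(symbols, lengths(entries))
  dup <- unique(surf[duplicated(surf)])
  ambiguous <- dup[vapply(dup, function(s)
    length(unique(owner[surf == s])) > 1L, logical(1))]
  if (length(ambiguous)) {
    if (collision == "error")
      stop("surface form(s) claimed by multiple symbols: ",
           paste(ambiguous, collapse = ", "))
    blocked <- union(blocked, ambiguous)
  }
  short <- setdiff(surf[nchar(surf) < min_nchar], whitelist)
  blocked <- union(blocked, short)

  keep <- !(surf %in% blocked) & nzchar(surf)
  surface_map <- stats::setNames(owner[keep], surf[keep])
  structure(
    list(entries = entries, blocklist = sort(blocked),
         surface_map = surface_map),
    class = "gene_lexicon"
  )
}

#' @export
print.gene_lexicon <- function(x, ...) {
  cat("gene_lexicon:", length(x$entries), "symbols,",
      length(x$surface_map), "matchable surfaces,",
      length(x$blocklist), "blocked\n")
  invisible(x)
}

#' Read a lexicon from TSV
#'
#' Expected columns: `symbol`, optional `synonyms` (pipe-separated),
#' optional `blocked` (logical/0-1 flag marking the whole row's surfaces as
#' blocked).
#'
#' @param path file path.
#' @inheritParams gene_lexicon
#' @return a `gene_lexicon`.
#' @export
read_lexicon <- function(path, whitelist = character(), min_nchar = 3L,
                         collision = c("blocklist", "error")) {
  df <- utils::read.delim(path, colClasses = "character", quote = "",
                          stringsAsFactors = FALSE)
  if (!"symbol" %in% names(df)) stop("lexicon needs a `symbol` column")
  syn <- if ("synonyms" %in% names(df)) {
    raw <- ifelse(is.na(df$synonyms), "", df$synonyms)
    lapply(strsplit(raw, "|", fixed = TRUE),
           function(s) s[!is.na(s) & nzchar(s)])
  } else NULL
  blocked <- character()
  if ("blocked" %in% names(df)) {
    flag <- df$blocked %in% c("1", "TRUE", "true", "yes")
    blocked <- toupper(unlist(c(df$symbol[flag],
                                if (!is.null(syn)) syn[flag])))
  }
  gene_lexicon(df$symbol, syn, blocked = blocked, whitelist = whitelist,
               min_nchar = min_nchar, collision = match.arg(collision))
}
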