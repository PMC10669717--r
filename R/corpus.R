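#' Construct an abstract corpus
#'
#' An abstract corpus is a plain `data.frame` with one row per abstract and
#' columns `record_id`, `title`, `body`, `year`. Rows missing an id or a
#' non-empty body are rejected; the number of rejected rows is reported via
#' a warning so silently lossy loads are visible.
#'
#' @param record_id character vector of unique identifiers (e.g. PMIDs).
#' @param title character vector of titles (may be empty strings).
#' @param body character vector of abstract text.
#' @param year integer vector of publication years.
#' @return a `data.frame` of class `abstract_corpus`.
#' @export
abstract_corpus <- function(record_id, title, body, year) {
  df <- data.frame(
    record_id = as.character(record_id),
    title     = as.character(title),
    body      = as.character(body),
    year      = as.integer(year),
    stringsAsFactors = FALSE
  )
  bad <- is.na(df$record_id) | df$record_id == "" |
    is.na(df$body) | df$body == "" | is.na(df$year)
  if (any(bad)) {
    warning(sum(bad), " malformed record(s) skipped (missing id, body or year)")
    df <- df[!bad, , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("abstract_corpus", "data.frame")
  df
}

#' Read a corpus in the line-delimited structured dialect
#'
#' One record per line, four tab-separated fields with a header line
#' `record_id<TAB>title<TAB>body<TAB>year`. Embedded tabs/newlines are not
#' permitted in fields (the writer never emits them).
#'
#' @param path file path.
#' @return an `abstract_corpus`.
#' @export
read_corpus <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", quote = "",
                          stringsAsFactors = FALSE)
  need <- c("record_id", "title", "body", "year")
  if (!all(need %in% names(df)))
    stop("corpus file must have columns: ", paste(need, collapse = ", "))
  abstract_corpus(df$record_id, df$title, df$body, df$year)
}

#' Write a corpus in the structured dialect
#'
#' Tabs and newlines inside fields are replaced by single spaces so that the
#' one-record-per-line contract holds.
#'
#' @param corpus an `abstract_corpus`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  flat <- corpus
  for (col in c("title", "body"))
    flat[[col]] <- gsub("[\t\r\n]+", " ", flat[[col]])
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a MEDLINE flat file
#'
#' Parses the tag-based MEDLINE export format. Only the `PMID`, `TI`, `AB`
#' and `DP` tags are used; continuation lines (leading whitespace) are
#' folded into the preceding tag. The year is the first four-digit run in
#' the `DP` field. Records lacking a PMID or abstract are skipped with a
#' warning (counted, as for [abstract_corpus()]).
#'
#' @param path file path.
#' @return an `abstract_corpus`.
#' @export
read_medline <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- list(); cur <- list(); tag <- NULL
  flush <- function(cur, recs) {
    if (length(cur)) recs[[length(recs) + 1L]] <- cur
    recs
  }
  for (ln in lines) {
    if (grepl("^\\s*$", ln)) {               # blank line ends a record
      recs <- flush(cur, recs); cur <- list(); tag <- NULL
    } else if (grepl("^[A-Z]{1,4}\\s*-", ln)) {
      tag <- sub("^([A-Z]{1,4})\\s*-.*$", "\\1", ln)
      val <- sub("^[A-Z]{1,4}\\s*-\\s*", "", ln)
      cur[[tag]] <- if (is.null(cur[[tag]])) val else paste(cur[[tag]], val)
    } else if (grepl("^\\s+", ln) && !is.null(tag)) {
      cur[[tag]] <- paste(cur[[tag]], trimws(ln))
    }
  }
  recs <- flush(cur, recs)
  if (!length(recs))
    return(abstract_corpus(character(), character(), character(), integer()))
  getf <- function(r, t) if (is.null(r[[t]])) NA_character_ else r[[t]]
  year <- vapply(recs, function(r) {
    dp <- getf(r, "DP")
    m <- regmatches(dp, regexpr("\\d{4}", dp))
    if (length(m) && !is.na(dp)) as.integer(m) else NA_integer_
  }, integer(1))
  abstract_corpus(
    record_id = vapply(recs, getf, character(1), t = "PMID"),
    title     = vapply(recs, function(r) {
      ti <- getf(r, "TI"); if (is.na(ti)) "" else ti
    }, character(1)),
    body      = vapply(recs, getf, character(1), t = "AB"),
    year      = year
  )
}

#' Curate an abstract corpus by keyword, year and exclusion filters
#'
#' Mirrors a manual literature-curation step as mechanical filters: a record
#' is retained iff (i) its year lies in `[year_min, year_max]`, (ii) at
#' least one keyword occurs as a case-insensitive substring of title or
#' body (an empty keyword list retains everything in range), and (iii) no
#' exclusion term occurs. Duplicate `record_id`s are collapsed to the first
#' occurrence; input order is preserved.
#'
#' @param records an `abstract_corpus` (or coercible data.frame).
#' @param keywords character vector of inclusion keywords; `character(0)`
#'   disables keyword filtering.
#' @param year_min,year_max inclusive year range.
#' @param exclusion_terms character vector of terms whose presence (in
#'   title or body, case-insensitive) rejects a record.
#' @return the curated `abstract_corpus`.
#' @export
curate_corpus <- function(records, keywords = character(),
                          year_min = 1990L, year_max = 2023L,
                          exclusion_terms = character()) {
  if (!nrow(records)) return(records)
  records <- records[!duplicated(records$record_id), , drop = FALSE]
  text <- tolower(paste(records$title, records$body))
  keep <- records$year >= year_min & records$year <= year_max
  if (length(keywords)) {
    has_kw <- rep(FALSE, nrow(records))
    for (kw in tolower(keywords))
      has_kw <- has_kw | grepl(kw, text, fixed = TRUE)
    keep <- keep & has_kw
  }
  if (length(exclusion_terms)) {
    for (ex in tolower(exclusion_terms))
      keep <- keep & !grepl(ex, text, fixed = TRUE)
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
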