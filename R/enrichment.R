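#' Read a GMT annotation collection
#'
#' Standard gene-set format: one term per line,
#' `term_id<TAB>description<TAB>gene1<TAB>gene2...`. Symbols are
#' uppercased; duplicate genes within a term collapse; empty gene sets and
#' duplicate term ids are errors.
#'
#' @param path file path.
#' @return object of class `annotation_collection`: named list term_id ->
#'   list(name, genes).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 1)
  if (anyDuplicated(ids))
    stop("duplicate term ids in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  terms <- lapply(parts, function(p) {
    genes <- unique(toupper(trimws(p[-(1:2)])))
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("empty gene set for term ", p[1])
    list(name = if (length(p) >= 2) p[2] else p[1], genes = genes)
  })
  structure(stats::setNames(terms, ids), class = "annotation_collection")
}

#' Build an annotation collection in code
#'
#' @param gene_sets named list: term_id -> character vector of genes.
#' @param names optional named character vector of term descriptions.
#' @return an `annotation_collection`.
#' @export
annotation_collection <- function(gene_sets, names = NULL) {
  if (is.null(base::names(gene_sets)) || anyDuplicated(base::names(gene_sets)))
    stop("gene_sets must have unique names")
  terms <- lapply(seq_along(gene_sets), function(i) {
    id <- base::names(gene_sets)[i]
    genes <- unique(toupper(gene_sets[[i]]))
    if (!length(genes)) stop("empty gene set for term ", id)
    list(name = if (!is.null(names) && id %in% base::names(names))
      names[[id]] else id, genes = genes)
  })
  structure(stats::setNames(terms, base::names(gene_sets)),
            class = "annotation_collection")
}

#' Hypergeometric upper-tail probability P(X >= k)
#'
#' Over-representation p-value: probability of drawing at least `k`
#' annotated genes when `n` genes are drawn without replacement from a
#' universe of `N` genes of which `K` carry the annotation. Computed as
#' `phyper(k - 1, K, N - K, n, lower.tail = FALSE)`, which accumulates
#' log-space terms and is numerically stable in the far tail.
#'
#' @param k observed overlap (`0 <= k <= min(K, n)`).
#' @param K annotated genes in the universe.
#' @param n query size.
#' @param N universe size.
#' @return the upper-tail probability, in (0, 1].
#' @export
hypergeometric_upper_tail <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n))
    stop("invalid hypergeometric parameters: k=", k, " K=", K,
         " n=", n, " N=", N)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis of a gene set against a GMT collection
#'
#' Each term's gene set is intersected with the universe; terms with at
#' least one query overlap get a hypergeometric upper-tail p-value.
#' Following the motivating study, significance is the *raw* p-value
#' against `alpha` (default 0.01); Benjamini-Hochberg adjusted p-values
#' are additionally reported when `adjust = TRUE` and then drive the
#' `significant` flag.
#'
#' @param query character vector of gene symbols (genes outside the
#'   universe are dropped with a warning).
#' @param collection an [annotation_collection()].
#' @param universe character vector of background gene symbols (e.g. the
#'   disease network's node set).
#' @param alpha significance cutoff on the p-value.
#' @param adjust apply Benjamini-Hochberg across the tested terms.
#' @return data.frame sorted by p ascending then term id: `term`, `name`,
#'   `k`, `K`, `n`, `N`, `p`, (`p_adjusted`,) `significant`.
#' @export
enrich <- function(query, collection, universe, alpha = 0.01,
                   adjust = FALSE) {
  universe <- unique(toupper(universe))
  if (!length(universe)) stop("universe is empty")
  query <- unique(toupper(query))
  outside <- setdiff(query, universe)
  if (length(outside))
    warning(length(outside), " query gene(s) outside the universe dropped")
  query <- intersect(query, universe)
  empty <- data.frame(term = character(), name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
  if (!length(query)) {
    warning("query empty after universe intersection")
    return(empty)
  }
  N <- length(universe); n <- length(query)
  rows <- lapply(names(collection), function(id) {
    genes <- intersect(collection[[id]]$genes, universe)
    k <- length(intersect(genes, query))
    if (k < 1L) return(NULL)
    K <- length(genes)
    data.frame(term = id, name = collection[[id]]$name, k = k, K = K,
               n = n, N = N,
               p = hypergeometric_upper_tail(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) return(empty)
  if (adjust) {
    out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
    out$significant <- out$p_adjusted < alpha
  } else {
    out$significant <- out$p < alpha
  }
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write enrichment results as TSV
#'
#' @param results data.frame from [enrich()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
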