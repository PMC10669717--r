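# Independent brute-force oracles used to validate the implementation.
# These deliberately share no code with the package internals.

# Position-by-position dictionary matcher: scan every start offset, try
# every surface by decreasing length, check boundaries by hand, resolve
# leftmost-longest. Returns symbols with 0-based half-open offsets.
oracle_match <- function(text, lexicon) {
  upper <- toupper(text)
  chars <- strsplit(upper, "")[[1]]
  is_alnum <- grepl("[0-9A-Z]", chars)
  surfaces <- names(lexicon$surface_map)
  surfaces <- surfaces[order(-nchar(surfaces), surfaces)]
  n <- length(chars)
  res <- list(); consumed <- 0L
  pos <- 1L
  while (pos <= n) {
    hit <- NULL
    if (pos > consumed) {
      for (s in surfaces) {
        len <- nchar(s)
        if (pos + len - 1L > n) next
        if (substr(upper, pos, pos + len - 1L) != s) next
        ok_before <- pos == 1L || !is_alnum[pos - 1L]
        ok_after <- pos + len > n || !is_alnum[pos + len]
        if (ok_before && ok_after) {
          hit <- list(symbol = unname(lexicon$surface_map[[s]]),
                      start = pos - 1L, end = pos - 1L + len)
          break
        }
      }
    }
    if (!is.null(hit)) {
      res[[length(res) + 1L]] <- hit
      consumed <- hit$end
    }
    pos <- pos + 1L
  }
  if (!length(res))
    return(data.frame(symbol = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  data.frame(symbol = vapply(res, `[[`, character(1), "symbol"),
             start = vapply(res, `[[`, integer(1), "start"),
             end = vapply(res, `[[`, integer(1), "end"),
             stringsAsFactors = FALSE)
}

# Exhaustive DFS over simple paths from `from` to `to` with at most
# `cutoff` edges, on an edge data.frame with columns a, b (undirected).
oracle_simple_paths <- function(edges, from, to, cutoff) {
  adj <- list()
  add <- function(x, y) {
    adj[[x]] <<- c(adj[[x]], y)
  }
  for (i in seq_len(nrow(edges))) {
    add(edges$a[i], edges$b[i]); add(edges$b[i], edges$a[i])
  }
  paths <- list()
  walk <- function(path) {
    head <- path[length(path)]
    if (head == to) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    if (length(path) - 1L >= cutoff) return(invisible())
    for (nb in adj[[head]]) {
      if (!nb %in% path) walk(c(path, nb))
    }
  }
  if (from == to) return(list(from))
  walk(from)
  paths
}

# P(X >= k) for X ~ Hypergeometric(N, K, n), by enumerating every one of
# the C(N, n) equally likely draws from a universe 1..N whose annotated
# genes are 1..K.
oracle_hyper_upper <- function(k, K, n, N) {
  if (k == 0) return(1)
  if (n == 0) return(0)
  draws <- utils::combn(N, n)
  overlap <- colSums(draws <= K)
  mean(overlap >= k)
}

# Studentized range CDF P(Q <= q) for k groups and df error degrees of
# freedom, by nested numerical integration of the defining double
# integral (s is the scaled chi distribution of the pooled SD).
oracle_ptukey <- function(q, k, df) {
  inner <- function(s) {
    f <- function(z)
      k * stats::dnorm(z) *
        (stats::pnorm(z) - stats::pnorm(z - q * s))^(k - 1)
    stats::integrate(f, -8, 8, rel.tol = 1e-10)$value
  }
  dens <- function(s)
    exp((df / 2) * log(df) - lgamma(df / 2) - (df / 2 - 1) * log(2) +
          (df - 1) * log(s) - df * s^2 / 2)
  out <- stats::integrate(function(sv)
    vapply(sv, function(s) dens(s) * inner(s), numeric(1)),
    0, Inf, rel.tol = 1e-9)
  out$value
}

# Connected components by union-find on an edge data.frame plus isolated
# nodes, returning sorted component sizes.
oracle_component_sizes <- function(nodes, edges) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (i in seq_len(nrow(edges))) {
    ra <- find(edges$a[i]); rb <- find(edges$b[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, character(1))
  sort(as.integer(table(roots)), decreasing = TRUE)
}

# Canonical string keys for a set of paths, for order-free comparison.
path_keys <- function(paths) {
  sort(vapply(paths, function(p) {
    nodes <- if (is.list(p) || inherits(p, "signal_path")) p$nodes else p
    paste(nodes, collapse = ">")
  }, character(1)))
}

# Small random test lexicon + helper to build random boundary-embedded
# texts with known planted hits.
toy_lexicon <- function() {
  gene_lexicon(c("BDNF", "KCNJ11", "AP2M1", "ESR1", "APP", "PRKAB1"),
               synonyms = list("brain-derived neurotrophic factor",
                               NULL, NULL, NULL,
                               "amyloid precursor protein", NULL))
}
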