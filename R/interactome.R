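#' Read a drug -> target receptor map
#'
#' TSV with columns `drug` and `receptor`; one row per (drug, receptor)
#' pair, several rows for multi-receptor drugs.
#'
#' @param path file path.
#' @return named list: drug -> character vector of receptor symbols.
#' @export
read_drug_targets <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", quote = "",
                          stringsAsFactors = FALSE)
  if (!all(c("drug", "receptor") %in% names(df)))
    stop("drug-target map needs `drug` and `receptor` columns")
  lapply(split(toupper(trimws(df$receptor)), df$drug), unique)
}

#' A receptor -> anchor signal path
#'
#' @param nodes ordered character vector from a receptor to the anchor.
#' @return object of class `signal_path` with fields `nodes` and `length`
#'   (edge count).
#' @export
signal_path <- function(nodes) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("signal path revisits a node")
  structure(list(nodes = nodes, length = length(nodes) - 1L),
            class = "signal_path")
}

#' @export
print.signal_path <- function(x, ...) {
  cat(paste(x$nodes, collapse = " -> "), " (", x$length, " hops)\n",
      sep = "")
  invisible(x)
}

#' Intermediary proteins of a signal path
#'
#' The path's nodes excluding the first (receptor) and last (anchor), in
#' path order; these are the genes taken forward for expression
#' validation.
#'
#' @param path a [signal_path()].
#' @return character vector (possibly empty).
#' @export
intermediaries <- function(path) {
  n <- length(path$nodes)
  if (n <= 2L) return(character())
  path$nodes[seq(2L, n - 1L)]
}

# receptors present in the network; error if none, warn on drops
.check_receptors <- function(net, receptors, anchor) {
  receptors <- unique(toupper(trimws(receptors)))
  anchor <- toupper(trimws(anchor))
  if (!anchor %in% net$nodes)
    stop("anchor ", anchor, " is not in the network")
  missing <- setdiff(receptors, net$nodes)
  if (length(missing))
    warning("receptor(s) not in network, skipped: ",
            paste(missing, collapse = ", "))
  present <- setdiff(receptors, missing)
  if (!length(present)) stop("no receptor is present in the network")
  list(receptors = present, anchor = anchor)
}

.path_key <- function(nodes) paste(nodes, collapse = "\t")

#' All minimum-hop receptor -> anchor signal cascades
#'
#' Enumerates every minimum-length simple path from any of the drug's
#' target receptors to the anchor protein in the undirected, unweighted
#' network ("shortest" is hop count). For multi-receptor drugs the minimum
#' is global across receptors by default. All ties are returned, sorted by
#' (length, lexicographic node sequence); the first element is the
#' canonical reported cascade. A receptor equal to the anchor yields the
#' single-node path of length 0.
#'
#' @param net a `protein_network`.
#' @param receptors character vector of target receptor symbols.
#' @param anchor anchor protein symbol (BDNF in the motivating study).
#' @param per_receptor if `TRUE`, return a named list of cascade lists,
#'   one per receptor, each holding that receptor's own minimum-hop paths.
#' @return list of [signal_path()] objects (empty, with a warning, when no
#'   receptor reaches the anchor).
#' @export
shortest_cascade <- function(net, receptors, anchor,
                             per_receptor = FALSE) {
  ck <- .check_receptors(net, receptors, anchor)
  paths_for <- function(r) {
    if (r == ck$anchor) return(list(signal_path(r)))
    res <- suppressWarnings(
      igraph::all_shortest_paths(net$graph, from = r, to = ck$anchor)
    )$res
    lapply(res, function(v) signal_path(names(v)))
  }
  sort_paths <- function(ps) {
    if (!length(ps)) return(ps)
    keys <- vapply(ps, function(p) .path_key(p$nodes), character(1))
    lens <- vapply(ps, function(p) p$length, integer(1))
    ps[order(lens, keys)]
  }
  per <- lapply(ck$receptors, paths_for)
  names(per) <- ck$receptors
  if (per_receptor) return(lapply(per, sort_paths))
  all_paths <- do.call(c, unname(per))
  if (!length(all_paths)) {
    warning("no receptor reaches the anchor; empty cascade set")
    return(list())
  }
  lens <- vapply(all_paths, function(p) p$length, integer(1))
  sort_paths(all_paths[lens == min(lens)])
}

#' Extract a drug's receptor-anchored interactome
#'
#' The interactome is the union of all simple receptor -> anchor paths of
#' at most `max_path_len` hops: its nodes are every protein on at least
#' one qualifying path and its edges are the network edges used by at
#' least one qualifying path. The default hop budget is the shortest
#' receptor -> anchor distance plus 2, a bounded neighbourhood around the
#' cascade; unbounded enumeration explodes combinatorially on dense
#' networks.
#'
#' @inheritParams shortest_cascade
#' @param drug drug name recorded in the result.
#' @param max_path_len hop budget (`NULL` = shortest distance + 2).
#' @return object of class `drug_interactome`: list with `drug`,
#'   `receptors`, `anchor`, `nodes`, `edges` (canonical data.frame),
#'   `max_path_len`, `cascades` (the [shortest_cascade()] set) and
#'   `empty` flag (TRUE, with a warning, when no path exists within
#'   budget).
#' @export
extract_interactome <- function(net, receptors, anchor,
                                max_path_len = NULL, drug = NA_character_) {
  ck <- .check_receptors(net, receptors, anchor)
  cascades <- withCallingHandlers(
    shortest_cascade(net, ck$receptors, ck$anchor),
    warning = function(w) invokeRestart("muffleWarning")
  )
  if (!length(cascades)) {
    warning("no receptor -> anchor path; empty interactome for ",
            if (is.na(drug)) "drug" else drug)
    return(structure(
      list(drug = drug, receptors = ck$receptors, anchor = ck$anchor,
           nodes = character(),
           edges = data.frame(a = character(), b = character(),
                              stringsAsFactors = FALSE),
           max_path_len = max_path_len, cascades = list(), empty = TRUE),
      class = "drug_interactome"))
  }
  if (is.null(max_path_len))
    max_path_len <- cascades[[1]]$length + 2L
  if (max_path_len < 1L) stop("max_path_len must be >= 1")
  nodes <- character(); ekeys <- character()
  ea <- character(); eb <- character()
  for (r in ck$receptors) {
    ps <- if (r == ck$anchor) list(ck$anchor) else
      lapply(igraph::all_simple_paths(net$graph, from = r, to = ck$anchor,
                                      cutoff = max_path_len),
             names)
    for (p in ps) {
      nodes <- union(nodes, p)
      if (length(p) > 1L) {
        x <- p[-length(p)]; y <- p[-1]
        key <- paste(pmin(x, y), pmax(x, y), sep = "\t")
        new <- !key %in% ekeys
        ekeys <- c(ekeys, key[new])
        ea <- c(ea, pmin(x, y)[new]); eb <- c(eb, pmax(x, y)[new])
      }
    }
  }
  if (!length(nodes)) {
    warning("no receptor -> anchor path within budget ", max_path_len,
            "; empty interactome for ", if (is.na(drug)) "drug" else drug)
    return(structure(
      list(drug = drug, receptors = ck$receptors, anchor = ck$anchor,
           nodes = character(),
           edges = data.frame(a = character(), b = character(),
                              stringsAsFactors = FALSE),
           max_path_len = as.integer(max_path_len), cascades = list(),
           empty = TRUE),
      class = "drug_interactome"))
  }
  edges <- data.frame(a = ea, b = eb, stringsAsFactors = FALSE)
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(
    list(drug = drug, receptors = ck$receptors, anchor = ck$anchor,
         nodes = sort(nodes), edges = edges,
         max_path_len = as.integer(max_path_len),
         cascades = cascades, empty = FALSE),
    class = "drug_interactome")
}

#' @export
print.drug_interactome <- function(x, ...) {
  cat("drug_interactome", if (!is.na(x$drug)) paste0("(", x$drug, ")"),
      ":", length(x$nodes), "nodes,", nrow(x$edges), "edges, budget",
      x$max_path_len, "\n")
  if (length(x$cascades)) {
    cat("canonical cascade: ")
    print(x$cascades[[1]])
  }
  invisible(x)
}

#' Export an interactome as JSON (and optionally SIF)
#'
#' @param x a `drug_interactome`.
#' @param json_path output JSON path (nodes, edges, cascades).
#' @param sif_path optional SIF path for the edge set.
#' @return `json_path`, invisibly.
#' @export
write_interactome <- function(x, json_path, sif_path = NULL) {
  obj <- list(
    drug = x$drug, receptors = x$receptors, anchor = x$anchor,
    max_path_len = x$max_path_len, nodes = x$nodes,
    edges = x$edges,
    cascades = lapply(x$cascades, function(p) p$nodes)
  )
  jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(sif_path)) write_sif(x, sif_path)
  invisible(json_path)
}
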