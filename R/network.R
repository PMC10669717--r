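#' Load a reference interaction catalogue
#'
#' Reads an undirected protein-protein edge list in either two-column TSV
#' (`a<TAB>b`, optional third column kept as provenance) or SIF
#' (`nodeA<TAB>interaction<TAB>nodeB`; the interaction type is recorded in
#' `source`, and SIF rows listing several partners after the interaction
#' type expand to one edge per partner). Symbols are uppercased, each edge
#' stored with endpoints in lexicographic order, self-loops and exact
#' duplicate edges dropped; the number of dropped records is reported in a
#' message.
#'
#' @param path file path.
#' @param format `"tsv"` or `"sif"`; `"auto"` picks SIF for `.sif` files.
#' @return data.frame with columns `a`, `b`, `source`; class
#'   `edge_catalogue`.
#' @export
load_edge_catalogue <- function(path, format = c("auto", "tsv", "sif")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "tsv"
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(edge_catalogue(character(), character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  a <- character(); b <- character(); src <- character()
  for (i in seq_along(parts)) {
    p <- trimws(parts[[i]])
    p <- p[nzchar(p)]
    if (format == "sif") {
      if (length(p) < 3L)
        stop("unparseable SIF line ", i, ": ", lines[i])
      for (partner in p[-(1:2)]) {
        a <- c(a, p[1]); b <- c(b, partner); src <- c(src, p[2])
      }
    } else {
      if (length(p) < 2L)
        stop("unparseable TSV edge line ", i, ": ", lines[i])
      a <- c(a, p[1]); b <- c(b, p[2])
      src <- c(src, if (length(p) >= 3L) p[3] else NA_character_)
    }
  }
  edge_catalogue(a, b, src)
}

#' Canonicalize an edge list into a catalogue
#'
#' @param a,b character vectors of endpoint symbols.
#' @param source optional provenance strings.
#' @return `edge_catalogue` data.frame.
#' @export
edge_catalogue <- function(a, b, source = NA_character_) {
  a <- toupper(trimws(a)); b <- toupper(trimws(b))
  if (!length(a)) source <- character()
  df <- data.frame(a = pmin(a, b), b = pmax(a, b),
                   source = source, stringsAsFactors = FALSE)
  n0 <- nrow(df)
  df <- df[df$a != df$b, , drop = FALSE]
  df <- df[!duplicated(df[c("a", "b")]), , drop = FALSE]
  dropped <- n0 - nrow(df)
  if (dropped > 0)
    message(dropped, " self-loop/duplicate edge record(s) dropped")
  rownames(df) <- NULL
  class(df) <- c("edge_catalogue", "data.frame")
  df
}

#' Induce the disease protein network on a mined protein list
#'
#' The disease network is the subgraph of the reference catalogue induced
#' on the mined symbols: edges whose BOTH endpoints were mined, plus (by
#' default) the mined proteins that touch no retained edge as isolated
#' degree-0 nodes, so the full mined list remains available as an
#' enrichment universe.
#'
#' @param proteins character vector of mined protein symbols (non-empty).
#' @param catalogue an [edge_catalogue()] (or 2-column data.frame).
#' @param keep_isolated retain mined proteins with no retained edge.
#' @return a `protein_network` object: list with `nodes`, `edges`
#'   (canonical data.frame) and `graph` (igraph, undirected simple).
#' @export
induce_disease_network <- function(proteins, catalogue,
                                   keep_isolated = TRUE) {
  if (!length(proteins)) stop("protein list is empty")
  proteins <- unique(toupper(trimws(proteins)))
  if (!inherits(catalogue, "edge_catalogue"))
    catalogue <- edge_catalogue(catalogue[[1]], catalogue[[2]])
  inside <- catalogue$a %in% proteins & catalogue$b %in% proteins
  edges <- catalogue[inside, c("a", "b"), drop = FALSE]
  rownames(edges) <- NULL
  nodes <- if (keep_isolated) sort(proteins)
           else sort(unique(c(edges$a, edges$b)))
  protein_network(nodes, edges)
}

#' Assemble a protein network from nodes and canonical edges
#'
#' @param nodes character vector of node symbols.
#' @param edges data.frame with columns `a`, `b` (already canonicalized;
#'   endpoints must be in `nodes`).
#' @return a `protein_network`.
#' @export
protein_network <- function(nodes, edges) {
  nodes <- sort(unique(nodes))
  stopifnot(all(c(edges$a, edges$b) %in% nodes))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "protein_network")
}

#' @export
print.protein_network <- function(x, ...) {
  cat("protein_network:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges\n")
  invisible(x)
}

#' Summarize a protein network
#'
#' @param net a `protein_network`.
#' @return list with `n_nodes`, `n_edges`, `degree` (min/median/max),
#'   `n_components`, `component_sizes` (decreasing).
#' @export
network_summary <- function(net) {
  if (!length(net$nodes))
    return(list(n_nodes = 0L, n_edges = 0L,
                degree = list(min = 0, median = 0, max = 0),
                n_components = 0L, component_sizes = integer()))
  deg <- igraph::degree(net$graph)
  comp <- igraph::components(net$graph)
  list(
    n_nodes = length(net$nodes),
    n_edges = nrow(net$edges),
    degree = list(min = min(deg), median = stats::median(deg),
                  max = max(deg)),
    n_components = comp$no,
    component_sizes = sort(as.integer(comp$csize), decreasing = TRUE)
  )
}

#' Write a network (or catalogue) as SIF
#'
#' @param x a `protein_network` or `edge_catalogue`.
#' @param path output path.
#' @param interaction interaction type written in the middle column.
#' @return `path`, invisibly.
#' @export
write_sif <- function(x, path, interaction = "pp") {
  edges <- if (inherits(x, "protein_network")) x$edges else x
  writeLines(paste(edges$a, interaction, edges$b, sep = "\t"), path)
  invisible(path)
}
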