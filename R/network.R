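#' Construct a gene network
#'
#' A weighted undirected simple graph over gene symbols. Edge weights are
#' interaction strengths (> 0); the transport ground metric uses edge length
#' = 1 / strength. Connected components get a stable index in node order.
#'
#' @param edges data.frame-like with columns `from`, `to` and optionally
#'   `strength` (positive; default 1). Repeated edges collapse keeping the
#'   maximum strength.
#' @param nodes optional character vector fixing node order; defaults to
#'   first-appearance order in `edges`. May include isolated genes.
#' @return A `gene_network` wrapping an igraph graph.
#' @export
gene_network <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) stop("edge table needs columns from, to")
  names(edges)[1:2] <- c("from", "to")
  if (ncol(edges) >= 3L) names(edges)[3L] <- "strength" else edges$strength <- 1
  edges$strength <- as.numeric(edges$strength)
  if (any(!is.finite(edges$strength)) || any(edges$strength <= 0))
    stop("edge strengths must be positive finite numbers")
  if (any(edges$from == edges$to))
    stop("self-loop edge not allowed: ",
         edges$from[match(TRUE, edges$from == edges$to)])
  if (is.null(nodes))
    nodes <- unique(as.vector(rbind(edges$from, edges$to)))
  # collapse duplicate (unordered) edges, keeping maximum strength
  key <- ifelse(edges$from < edges$to,
                paste(edges$from, edges$to, sep = "\r"),
                paste(edges$to, edges$from, sep = "\r"))
  keep <- tapply(edges$strength, key, max)
  parts <- strsplit(names(keep), "\r", fixed = TRUE)
  el <- data.frame(from = vapply(parts, `[`, "", 1L),
                   to = vapply(parts, `[`, "", 2L),
                   strength = as.numeric(keep), stringsAsFactors = FALSE)
  # restore first-appearance edge order
  el <- el[order(match(paste(el$from, el$to), paste(el$from, el$to))), ]
  gr <- igraph::graph_from_data_frame(el, directed = FALSE,
                                      vertices = data.frame(name = nodes))
  igraph::E(gr)$length <- 1 / igraph::E(gr)$strength
  comp <- igraph::components(gr)
  structure(list(graph = gr, nodes = nodes, membership = comp$membership),
            class = "gene_network")
}

#' @rdname gene_network
#' @param x object to test.
#' @export
is_gene_network <- function(x) inherits(x, "gene_network")

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network> %d genes, %d edges, %d component(s)\n",
              length(x$nodes), igraph::ecount(x$graph),
              max(x$membership)))
  invisible(x)
}

#' Network accessors
#'
#' `network_nodes` returns the gene symbols in node order;
#' `network_components` the list of per-component gene vectors (stable
#' indices, in node order).
#'
#' @param g a [gene_network()].
#' @export
network_nodes <- function(g) g$nodes

#' @rdname network_nodes
#' @export
network_components <- function(g) {
  split(g$nodes, g$membership)
}

#' Read a gene network from an edge list
#'
#' Whitespace-delimited rows `gene_a gene_b [strength]` (SIF-like). Repeated
#' edges collapse to the maximum strength; self-loops and non-positive
#' strengths are rejected.
#'
#' @param path file path.
#' @return A [gene_network()].
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("edge list is empty")
  fields <- strsplit(trimws(lines), "[ \t]+")
  n <- lengths(fields)
  if (any(n < 2L | n > 3L))
    stop("each row must have 2 or 3 fields; row ",
         match(TRUE, n < 2L | n > 3L), " has ", n[match(TRUE, n < 2L | n > 3L)])
  from <- vapply(fields, `[`, "", 1L)
  to <- vapply(fields, `[`, "", 2L)
  s <- vapply(fields, function(f) if (length(f) == 3L) f[3L] else "1", "")
  strength <- suppressWarnings(as.numeric(s))
  if (any(!is.finite(strength)))
    stop("non-numeric strength at row ", match(TRUE, !is.finite(strength)))
  gene_network(data.frame(from = from, to = to, strength = strength,
                          stringsAsFactors = FALSE))
}

#' Write a network as GraphML for external viewers
#'
#' @param g a [gene_network()].
#' @param path output path.
#' @export
write_network_graphml <- function(g, path) {
  stopifnot(is_gene_network(g))
  igraph::write_graph(g$graph, path, format = "graphml")
  invisible(path)
}

#' Shortest-path ground metric of a gene network
#'
#' Per connected component, the all-pairs shortest-path distance matrix with
#' edge length equal to the reciprocal of the edge strength (length 1 for
#' unweighted edges). This is the ground metric the Wasserstein-1 transport
#' cost is measured against.
#'
#' @param g a [gene_network()].
#' @return A `ground_metric`: list of symmetric matrices, one per component,
#'   rows/columns named by gene.
#' @export
ground_metric <- function(g) {
  stopifnot(is_gene_network(g))
  comps <- network_components(g)
  mats <- lapply(comps, function(genes) {
    sub <- igraph::induced_subgraph(g$graph, genes)
    d <- igraph::distances(sub, weights = igraph::E(sub)$length)
    d[genes, genes, drop = FALSE]
  })
  structure(mats, class = "ground_metric")
}
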