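#' Build a tissue interactome from PPI records and an expressed-gene universe
#'
#' Restricts a parsed PPI edge list to interactions whose two endpoints both
#' belong to the expressed-gene universe, then cleans the graph: duplicate
#' records (in either orientation) collapse to one undirected edge, self-loops
#' are removed, and nodes left with degree zero are dropped. Every surviving
#' edge carries `ppi = TRUE` and `coexpr = FALSE` until
#' [annotate_coexpression()] is applied.
#'
#' @param ppi_records Data frame from [read_edge_list()] (columns `gene_a`,
#'   `gene_b`).
#' @param expressed Expressed-gene universe: a [gene_set()] or character
#'   vector.
#' @return An igraph object of class `tissue_interactome` with logical edge
#'   attributes `ppi`/`coexpr` and graph attributes `n_input_records`,
#'   `n_kept_records`.
#' @export
build_tissue_interactome <- function(ppi_records, expressed) {
  expressed <- as_genes(expressed)
  if (!length(expressed)) stop_fmt("expressed universe is empty")
  a <- ppi_records$gene_a
  b <- ppi_records$gene_b
  keep <- a %in% expressed & b %in% expressed & a != b
  a <- a[keep]; b <- b[keep]
  keys <- pair_key(a, b)
  first <- !duplicated(keys)
  a <- a[first]; b <- b[first]
  if (!length(a)) {
    warn_fmt("tissue interactome is empty: no PPI edge has both endpoints expressed")
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      data.frame(from = a, to = b, stringsAsFactors = FALSE),
      directed = FALSE
    )
    igraph::E(g)$ppi <- TRUE
    igraph::E(g)$coexpr <- FALSE
  }
  # nodes come from edges only, so degree-zero pruning is already implied
  g <- igraph::set_graph_attr(g, "n_input_records", nrow(ppi_records))
  g <- igraph::set_graph_attr(g, "n_kept_records", sum(keep))
  class(g) <- c("tissue_interactome", class(g))
  g
}

#' Flag interactome edges supported by co-expression
#'
#' Sets `coexpr = TRUE` on every interactome edge whose gene pair passes the
#' co-expression cutoff. Co-expression is an edge *attribute*, never an edge
#' source: the topology is unchanged, and pairs co-expressed without a
#' physical interaction do not appear.
#'
#' @param network A `tissue_interactome` (see [build_tissue_interactome()]).
#' @param coexpr_edges A `coexpression_edges` data frame
#'   (see [coexpression_edges()]).
#' @return The network with updated `coexpr` edge flags.
#' @export
annotate_coexpression <- function(network, coexpr_edges) {
  if (igraph::ecount(network) == 0L) return(network)
  el <- igraph::as_edgelist(network, names = TRUE)
  net_keys <- pair_key(el[, 1L], el[, 2L])
  co_keys <- pair_key(coexpr_edges$gene_a, coexpr_edges$gene_b)
  igraph::E(network)$coexpr <- net_keys %in% co_keys
  network
}

#' @export
print.tissue_interactome <- function(x, ...) {
  ne <- igraph::ecount(x)
  nd <- if (ne) sum(igraph::E(x)$ppi & igraph::E(x)$coexpr) else 0L
  cat(sprintf("<tissue_interactome> %d nodes, %d edges (%d dual-support)\n",
              igraph::vcount(x), ne, nd))
  invisible(x)
}

#' Node/edge counts of a network
#'
#' @param network An igraph object.
#' @return Named list with `nodes`, `edges`, and `dual_support` (edges with
#'   both `ppi` and `coexpr` flags).
#' @export
network_summary <- function(network) {
  ne <- igraph::ecount(network)
  list(
    nodes = igraph::vcount(network),
    edges = ne,
    dual_support = if (ne) sum(E_attr(network, "ppi", TRUE) &
                                 E_attr(network, "coexpr", FALSE)) else 0L
  )
}
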