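# Shared fast-path extraction. Works on an integer edge list so that the
# permutation null can run thousands of replicates without rebuilding igraph
# objects; extract_seed_subnetwork() wraps the same rule, so the observed
# statistic and the null replicates use one extraction implementation.
#
# Rule: nodes = seeds present in the network plus every first neighbor reached
# from a seed through a dual-support (ppi AND coexpr) edge; edges = ALL
# network edges induced on that node set (PPI-only edges among recruited
# nodes included); nodes left with zero induced degree are pruned.
extract_core <- function(el, dual, seed_vertex, n_vertices) {
  is_seed <- logical(n_vertices)
  is_seed[seed_vertex] <- TRUE
  a <- el[, 1L]
  b <- el[, 2L]
  in_set <- is_seed
  in_set[b[dual & is_seed[a]]] <- TRUE
  in_set[a[dual & is_seed[b]]] <- TRUE
  induced <- in_set[a] & in_set[b]
  kept_vertices <- unique(c(a[induced], b[induced]))
  list(vertices = kept_vertices, edge_idx = which(induced),
       n_nodes = length(kept_vertices), n_edges = sum(induced))
}

interactome_parts <- function(interactome) {
  el <- igraph::as_edgelist(interactome, names = FALSE)
  storage.mode(el) <- "integer"
  ne <- igraph::ecount(interactome)
  dual <- if (ne) E_attr(interactome, "ppi", TRUE) &
    E_attr(interactome, "coexpr", FALSE) else logical()
  list(el = el, dual = dual, n = igraph::vcount(interactome),
       names = igraph::V(interactome)$name)
}

#' Extract a seed subnetwork with dual-support neighbor recruitment
#'
#' Maps a seed gene set onto an annotated tissue interactome and extracts the
#' subnetwork containing (i) the seeds present in the interactome and (ii)
#' their first neighbors connected to a seed by a dual-support edge (physical
#' interaction AND co-expression). The edge set is every interactome edge
#' induced on those nodes — recruitment requires dual support, but induced
#' PPI-only edges are retained. Nodes with zero induced degree are pruned.
#'
#' @param interactome A `tissue_interactome`, annotated via
#'   [annotate_coexpression()].
#' @param seeds A [gene_set()] (regulation labels, when present, are copied
#'   onto the nodes) or character vector.
#' @return An igraph of class `seed_subnetwork` with vertex attributes `role`
#'   (`"seed"`/`"neighbor"`) and `regulation` (`"up"`/`"down"`/`"none"`), and
#'   graph attribute `seed_set_name`.
#' @export
extract_seed_subnetwork <- function(interactome, seeds) {
  seed_name <- if (inherits(seeds, "gene_set")) seeds$name else "seeds"
  reg <- if (inherits(seeds, "gene_set")) seeds$regulation else NULL
  seed_genes <- as_genes(seeds)
  parts <- interactome_parts(interactome)
  seed_vertex <- which(parts$names %in% seed_genes)
  if (!length(seed_vertex)) {
    warn_fmt("no seed of '%s' is present in the interactome", seed_name)
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    core <- extract_core(parts$el, parts$dual, seed_vertex, parts$n)
    g <- igraph::subgraph_from_edges(interactome,
                                     eids = core$edge_idx,
                                     delete.vertices = TRUE)
  }
  nm <- igraph::V(g)$name %||% character()
  igraph::V(g)$role <- ifelse(nm %in% seed_genes, "seed", "neighbor")
  node_reg <- rep("none", length(nm))
  if (!is.null(reg)) {
    hit <- nm %in% names(reg)
    node_reg[hit] <- unname(reg[nm[hit]])
  }
  igraph::V(g)$regulation <- node_reg
  g <- igraph::set_graph_attr(g, "seed_set_name", seed_name)
  class(g) <- c("seed_subnetwork", setdiff(class(g), "seed_subnetwork"))
  g
}

#' @export
print.seed_subnetwork <- function(x, ...) {
  cat(sprintf("<seed_subnetwork '%s'> %d nodes (%d seeds), %d edges\n",
              igraph::graph_attr(x, "seed_set_name") %||% "?",
              igraph::vcount(x),
              sum(V_attr(x, "role", "none") == "seed"),
              igraph::ecount(x)))
  invisible(x)
}

#' Node-shuffle permutation null for subnetwork size
#'
#' Assesses whether an observed seed subnetwork is larger than expected by
#' chance. Each replicate applies a uniform random permutation of the node
#' labels to the fixed interactome topology (support flags stay attached to
#' the topology's edges), re-extracts the subnetwork for the same seed list,
#' and records its node and edge counts. The empirical p-value uses the
#' add-one estimator `p = (1 + #{replicates >= observed}) / (reps + 1)`, so it
#' is never exactly zero.
#'
#' @param interactome Annotated `tissue_interactome`.
#' @param seeds Seed [gene_set()] or character vector.
#' @param reps Number of label permutations (default 1000).
#' @param rng_seed Master seed; replicate `i` uses the derived stream
#'   `rng_seed + i`, so results do not depend on execution order.
#' @return An object of class `shuffle_null`: list with
#'   `replicate_node_counts`, `replicate_edge_counts`, `observed_nodes`,
#'   `observed_edges`, `reps`, `rng_seed`, `p_nodes`, `p_edges`, and
#'   `degenerate` (TRUE when every replicate has identical size, e.g. on
#'   vertex-transitive graphs).
#' @export
shuffle_null <- function(interactome, seeds, reps = 1000, rng_seed = 1) {
  stopifnot(reps >= 1)
  seed_genes <- as_genes(seeds)
  parts <- interactome_parts(interactome)
  seed_vertex <- which(parts$names %in% seed_genes)
  obs <- extract_core(parts$el, parts$dual, seed_vertex, parts$n)
  n_seed <- length(seed_vertex)
  node_counts <- integer(reps)
  edge_counts <- integer(reps)
  for (i in seq_len(reps)) {
    # permuting labels and re-mapping the seed list is equivalent to placing
    # the |seeds ∩ V| seed labels on a uniformly chosen vertex subset
    perm_seed <- with_seed(rng_seed + i, {
      relabel <- sample.int(parts$n)           # relabel[v] = new label index
      which(relabel <= n_seed)                 # vertices carrying seed labels
    })
    rep_core <- extract_core(parts$el, parts$dual, perm_seed, parts$n)
    node_counts[i] <- rep_core$n_nodes
    edge_counts[i] <- rep_core$n_edges
  }
  degenerate <- length(unique(node_counts)) == 1L &&
    length(unique(edge_counts)) == 1L
  if (degenerate) {
    warn_fmt("shuffle_null: degenerate null (all %d replicates identical)", reps)
  }
  structure(list(
    replicate_node_counts = node_counts,
    replicate_edge_counts = edge_counts,
    observed_nodes = obs$n_nodes,
    observed_edges = obs$n_edges,
    reps = reps,
    rng_seed = rng_seed,
    p_nodes = (1 + sum(node_counts >= obs$n_nodes)) / (reps + 1),
    p_edges = (1 + sum(edge_counts >= obs$n_edges)) / (reps + 1),
    degenerate = degenerate
  ), class = "shuffle_null")
}

#' @export
print.shuffle_null <- function(x, ...) {
  cat(sprintf(paste0("<shuffle_null> observed %d nodes / %d edges; ",
                     "%d reps; p_nodes = %.4g, p_edges = %.4g%s\n"),
              x$observed_nodes, x$observed_edges, x$reps,
              x$p_nodes, x$p_edges,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Betweenness-centrality hub ranking
#'
#' Unweighted, undirected shortest-path betweenness (unnormalized — rankings
#' are normalization-invariant). Ties are broken by descending degree, then
#' lexicographic gene symbol.
#'
#' @param subnetwork A non-empty igraph (typically a `seed_subnetwork`).
#' @param k Number of top genes to return (default 10); if `k` exceeds the
#'   node count, all nodes are returned with a warning.
#' @return Data frame with columns `gene`, `betweenness`, `degree`, ordered by
#'   rank.
#' @export
betweenness_ranking <- function(subnetwork, k = 10) {
  n <- igraph::vcount(subnetwork)
  if (n == 0L) stop_fmt("betweenness_ranking: empty subnetwork")
  if (k > n) {
    warn_fmt("k = %d exceeds node count %d; returning all nodes", k, n)
    k <- n
  }
  btw <- igraph::betweenness(subnetwork, directed = FALSE, weights = NA,
                             normalized = FALSE)
  deg <- igraph::degree(subnetwork)
  nm <- igraph::V(subnetwork)$name
  ord <- order(-btw, -deg, nm)
  out <- data.frame(gene = nm[ord], betweenness = unname(btw[ord]),
                    degree = unname(deg[ord]), stringsAsFactors = FALSE)
  utils::head(out, k)
}

#' Converged module shared by several subnetworks
#'
#' Intersects the node sets of two or more subnetworks extracted from the same
#' interactome and returns the interactome subgraph induced on the shared
#' nodes, together with a Venn-style overlap table (every pairwise and the
#' all-way intersection).
#'
#' @param subnetworks List of `seed_subnetwork` objects (length >= 2).
#' @param interactome The common `tissue_interactome`.
#' @return List of class `converged_module` with elements `module` (induced
#'   igraph; empty when the intersection is empty), `shared_nodes` (character)
#'   and `overlap` (data frame `sets`/`n_nodes`).
#' @export
converged_module <- function(subnetworks, interactome) {
  if (length(subnetworks) < 2L) stop_fmt("need at least two subnetworks")
  node_sets <- lapply(subnetworks, function(g) igraph::V(g)$name %||% character())
  set_names <- vapply(seq_along(subnetworks), function(i) {
    igraph::graph_attr(subnetworks[[i]], "seed_set_name") %||% paste0("set", i)
  }, "")
  names(node_sets) <- set_names
  shared <- Reduce(intersect, node_sets)
  combos <- utils::combn(seq_along(node_sets), 2, simplify = FALSE)
  overlap <- data.frame(
    sets = c(vapply(combos, function(ix) paste(set_names[ix], collapse = "&"), ""),
             paste(set_names, collapse = "&")),
    n_nodes = c(vapply(combos, function(ix) {
      length(Reduce(intersect, node_sets[ix]))
    }, 0L), length(shared)),
    stringsAsFactors = FALSE
  )
  module <- igraph::induced_subgraph(interactome,
                                     which(igraph::V(interactome)$name %in% shared))
  structure(list(module = module, shared_nodes = shared, overlap = overlap),
            class = "converged_module")
}

#' @export
print.converged_module <- function(x, ...) {
  cat(sprintf("<converged_module> %d shared nodes, %d induced edges\n",
              length(x$shared_nodes), igraph::ecount(x$module)))
  print(x$overlap, row.names = FALSE)
  invisible(x)
}
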