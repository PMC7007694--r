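#' Build a gene-pathway bipartite network restricted to a gene universe
#'
#' A strictly two-mode graph: membership edges link genes to the pathways
#' annotating them. Memberships are restricted to the supplied universe
#' (typically the expressed-gene set); pathways left without members are
#' dropped.
#'
#' @param gmt_records A `gmt` object from [read_gmt()] or [simulate_pathways()].
#' @param universe Gene universe ([gene_set()] or character vector).
#' @return Object of class `pathway_bipartite`: list with `edges` (data frame
#'   `gene`/`pathway`), `genes`, `pathways`, and `pathway_members` (named list
#'   of restricted member vectors).
#' @export
build_bipartite <- function(gmt_records, universe) {
  u <- as_genes(universe)
  if (!length(u)) stop_fmt("build_bipartite: empty universe")
  members <- lapply(gmt_records, function(r) intersect(r$members, u))
  names(members) <- vapply(gmt_records, `[[`, "", "pathway_id")
  members <- members[lengths(members) > 0L]
  edges <- if (length(members)) {
    data.frame(
      gene = unlist(members, use.names = FALSE),
      pathway = rep(names(members), lengths(members)),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(gene = character(), pathway = character(),
               stringsAsFactors = FALSE)
  }
  structure(list(
    edges = edges,
    genes = unique(edges$gene),
    pathways = names(members),
    pathway_members = members
  ), class = "pathway_bipartite")
}

#' @export
print.pathway_bipartite <- function(x, ...) {
  cat(sprintf("<pathway_bipartite> %d genes, %d pathways, %d membership edges\n",
              length(x$genes), length(x$pathways), nrow(x$edges)))
  invisible(x)
}

#' Per-pathway over-representation of seed genes
#'
#' One-sided hypergeometric tail test for each pathway: with population `N`
#' (genes in the bipartite network, or an explicitly supplied universe),
#' `m` pathway members, `n` seeds in the population, and `x` observed seed
#' members, `p = P(X >= x)`. A pathway is kept when `p < p_cut` AND it
#' contains at least `min_hits` seed genes — strict threshold semantics
#' (`< 1e-6`, `>= 10` by default).
#'
#' @param bipartite A [build_bipartite()] result.
#' @param seeds Seed [gene_set()] or character vector; seeds outside the
#'   population are dropped with a warning.
#' @param p_cut Keep threshold on the hypergeometric tail (default `1e-6`).
#' @param min_hits Minimum seed hits within the pathway (default 10).
#' @param universe_genes Optional explicit population (e.g. the full expressed
#'   universe) instead of the bipartite network's gene set.
#' @return Data frame of class `pathway_enrichment`, one row per pathway:
#'   `pathway_id`, `m`, `x`, `n`, `N`, `p_hyper`, `kept`.
#' @export
pathway_enrichment <- function(bipartite, seeds, p_cut = 1e-6, min_hits = 10,
                               universe_genes = NULL) {
  pop <- if (is.null(universe_genes)) bipartite$genes else as_genes(universe_genes)
  N <- length(pop)
  s <- as_genes(seeds)
  dropped <- setdiff(s, pop)
  if (length(dropped)) {
    warn_fmt("pathway_enrichment: %d seed(s) outside the population dropped",
             length(dropped))
  }
  s <- intersect(s, pop)
  n <- length(s)
  ids <- bipartite$pathways
  m <- lengths(bipartite$pathway_members)[ids]
  x <- vapply(bipartite$pathway_members[ids],
              function(mem) length(intersect(mem, s)), 0L)
  p <- stats::phyper(x - 1, m, N - m, n, lower.tail = FALSE)
  out <- data.frame(
    pathway_id = ids, m = unname(m), x = unname(x), n = n, N = N,
    p_hyper = unname(p),
    kept = unname(p < p_cut & x >= min_hits),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("pathway_enrichment", class(out))
  out
}

#' Restrict a bipartite network to kept pathways and their seed genes
#'
#' The seed-set-specific bipartite subnetwork: pathway nodes are the kept
#' pathways, gene nodes are seed genes with at least one membership edge to a
#' kept pathway.
#'
#' @param bipartite A [build_bipartite()] result.
#' @param rows [pathway_enrichment()] rows for the same bipartite network.
#' @param seeds The seed set the rows were computed for.
#' @return A `pathway_bipartite` restricted as described.
#' @export
bipartite_subnetwork <- function(bipartite, rows, seeds) {
  kept <- rows$pathway_id[rows$kept]
  s <- as_genes(seeds)
  members <- lapply(bipartite$pathway_members[kept],
                    function(mem) intersect(mem, s))
  members <- members[lengths(members) > 0L]
  edges <- if (length(members)) {
    data.frame(
      gene = unlist(members, use.names = FALSE),
      pathway = rep(names(members), lengths(members)),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(gene = character(), pathway = character(),
               stringsAsFactors = FALSE)
  }
  structure(list(
    edges = edges,
    genes = unique(edges$gene),
    pathways = names(members),
    pathway_members = members
  ), class = "pathway_bipartite")
}

#' Converged gene-pathway module shared by several bipartite subnetworks
#'
#' Pathway nodes are the intersection of the kept-pathway sets; gene nodes are
#' the intersection of the gene-node sets; membership edges are induced. Hub
#' genes are reported by pathway degree (the number of shared pathways each
#' gene connects to).
#'
#' @param subnetworks List of >= 2 `pathway_bipartite` subnetworks (from
#'   [bipartite_subnetwork()]).
#' @return List of class `converged_pathway_module`: `module` (a
#'   `pathway_bipartite`) and `gene_hubs` (data frame `gene`/`n_pathways`,
#'   sorted by descending degree).
#' @export
converged_pathway_module <- function(subnetworks) {
  if (length(subnetworks) < 2L) stop_fmt("need at least two bipartite subnetworks")
  shared_paths <- Reduce(intersect, lapply(subnetworks, `[[`, "pathways"))
  shared_genes <- Reduce(intersect, lapply(subnetworks, `[[`, "genes"))
  members <- lapply(subnetworks[[1L]]$pathway_members[shared_paths],
                    function(mem) intersect(mem, shared_genes))
  members <- members[lengths(members) > 0L]
  edges <- if (length(members)) {
    data.frame(
      gene = unlist(members, use.names = FALSE),
      pathway = rep(names(members), lengths(members)),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(gene = character(), pathway = character(),
               stringsAsFactors = FALSE)
  }
  module <- structure(list(
    edges = edges, genes = unique(edges$gene), pathways = names(members),
    pathway_members = members
  ), class = "pathway_bipartite")
  hubs <- if (nrow(edges)) {
    tab <- sort(table(edges$gene), decreasing = TRUE)
    data.frame(gene = names(tab), n_pathways = as.integer(tab),
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene = character(), n_pathways = integer(),
               stringsAsFactors = FALSE)
  }
  structure(list(module = module, gene_hubs = hubs),
            class = "converged_pathway_module")
}

#' Overlap between two enriched-pathway lists
#'
#' Reports how many pathways of `list_a` also appear in `list_b`, as a count
#' and a percentage of `|list_a|` (one decimal). Used to compare the pathways
#' enriched in a gene-pathway bipartite subnetwork with those enriched in the
#' corresponding PPI subnetwork.
#'
#' @param list_a,list_b Character vectors of pathway ids; `list_a` must be
#'   non-empty.
#' @return List with `n_a`, `n_overlap`, `percent`.
#' @export
pathway_list_overlap <- function(list_a, list_b) {
  a <- unique(as.character(list_a))
  if (!length(a)) stop_fmt("pathway_list_overlap: empty reference list")
  b <- unique(as.character(list_b))
  n_overlap <- length(intersect(a, b))
  list(n_a = length(a), n_overlap = n_overlap,
       percent = round(100 * n_overlap / length(a), 1))
}
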