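#' Read an undirected PPI edge list (BioGRID-like TSV)
#'
#' Parses a tab-separated interaction file with a header. The two gene-symbol
#' columns are located through `column_map`, so BioGRID tab3 exports
#' (`Official Symbol Interactor A`/`B`) and plain two-column files are both
#' accepted. Parsing is deliberately pure: duplicate rows and self-loops are
#' preserved here and collapsed/cleaned later by [build_tissue_interactome()].
#'
#' @param path Path to a TSV file with a header row.
#' @param column_map Named character vector mapping the fields `gene_a` and
#'   `gene_b` (optionally `source_tag`) to column names in the file.
#' @return A data frame with columns `gene_a`, `gene_b`, `source_tag`, one row
#'   per data row in file order; symbols whitespace-trimmed and
#'   case-normalized.
#' @export
read_edge_list <- function(path,
                           column_map = c(gene_a = "gene_a", gene_b = "gene_b")) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  column_map <- as.list(column_map)
  for (field in c("gene_a", "gene_b")) {
    col <- column_map[[field]]
    if (is.null(col) || !col %in% names(df)) {
      stop_fmt("edge list '%s': mapped column '%s' (for %s) not found",
               path, col %||% "<unmapped>", field)
    }
  }
  if (nrow(df) == 0L) {
    warn_fmt("edge list '%s' has no data rows", path)
    return(data.frame(gene_a = character(), gene_b = character(),
                      source_tag = character(), stringsAsFactors = FALSE))
  }
  src_col <- column_map[["source_tag"]]
  src <- if (!is.null(src_col) && src_col %in% names(df)) {
    as.character(df[[src_col]])
  } else rep("", nrow(df))
  out <- data.frame(
    gene_a = normalize_symbol(df[[column_map[["gene_a"]]]]),
    gene_b = normalize_symbol(df[[column_map[["gene_b"]]]]),
    source_tag = src,
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(out$gene_a)) || any(!nzchar(out$gene_b))) {
    stop_fmt("edge list '%s': empty gene symbol in data rows", path)
  }
  out
}

#' Read a plain-text gene list with optional regulation labels
#'
#' One symbol per line; an optional second tab-separated column carries a
#' regulation label (`up`/`down`). Duplicate symbols are collapsed with a
#' warning; the same gene carrying both `up` and `down` is an error.
#'
#' @param path Path to the list file.
#' @param name Name for the resulting set (default: file name sans extension).
#' @return A [gene_set()].
#' @export
read_gene_list <- function(path, name = NULL) {
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warn_fmt("gene list '%s' is empty", path)
    return(gene_set(character(), name = name))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  genes <- normalize_symbol(vapply(parts, `[[`, "", 1L))
  labels <- vapply(parts, function(p) if (length(p) >= 2L) trimws(p[[2L]]) else "", "")
  has_lab <- nzchar(labels)
  if (any(has_lab)) {
    bad <- setdiff(unique(labels[has_lab]), c("up", "down"))
    if (length(bad)) {
      stop_fmt("gene list '%s': unknown regulation label(s) %s",
               path, paste(bad, collapse = ", "))
    }
  }
  if (anyDuplicated(genes)) {
    warn_fmt("gene list '%s': %d duplicate symbol(s) collapsed",
             path, sum(duplicated(genes)))
  }
  reg <- NULL
  if (any(has_lab)) {
    reg <- labels[has_lab]
    names(reg) <- genes[has_lab]
    # conflicting labels detected by the gene_set constructor
  }
  gene_set(genes, regulation = reg, name = name, normalize = FALSE)
}

#' Read pathway annotations in GMT format
#'
#' Broad-dialect GMT: `pathway_id<TAB>description<TAB>gene1<TAB>gene2...`.
#' Member lists are deduplicated; records are returned in file order.
#'
#' @param path Path to a GMT file.
#' @return A list of class `gmt`; each element is a list with `pathway_id`,
#'   `description`, `members` (unique, case-normalized symbols).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    p <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(p) < 3L) {
      stop_fmt("GMT '%s': line %d has %d field(s), expected >= 3",
               path, i, length(p))
    }
    members <- unique(normalize_symbol(p[-(1:2)]))
    members <- members[nzchar(members)]
    if (!length(members)) stop_fmt("GMT '%s': line %d has no members", path, i)
    recs[[i]] <- list(pathway_id = p[[1L]], description = p[[2L]],
                      members = members)
  }
  ids <- vapply(recs, `[[`, "", "pathway_id")
  if (anyDuplicated(ids)) {
    stop_fmt("GMT '%s': duplicated pathway id(s): %s", path,
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  structure(recs, class = "gmt")
}

#' Write pathway annotations in GMT format
#'
#' @param gmt A `gmt` object (see [read_gmt()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gmt, path) {
  lines <- vapply(gmt, function(r) {
    paste(c(r$pathway_id, r$description, r$members), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write / read an interaction network as node and edge TSVs
#'
#' `write_network()` writes `<path>.edges.tsv` (columns `gene_a`, `gene_b`,
#' `support` with values `ppi`, `coexpr` or `both`) and `<path>.nodes.tsv`
#' (columns `gene`, `role`, `regulation`). `read_network()` reconstructs an
#' isomorphic labeled graph; a write/read round trip is the identity on node
#' set, edge multiset and attributes.
#'
#' @param network An igraph object with logical edge attributes `ppi` and
#'   `coexpr` (as produced by [build_tissue_interactome()] or
#'   [extract_seed_subnetwork()]).
#' @param path Output path prefix (no extension).
#' @return For `write_network()`, `path` invisibly; for `read_network()`, the
#'   reconstructed igraph.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "igraph"))
  el <- igraph::as_edgelist(network, names = TRUE)
  ne <- nrow(el)
  ppi <- if (ne) E_attr(network, "ppi", TRUE) else logical()
  cox <- if (ne) E_attr(network, "coexpr", FALSE) else logical()
  support <- ifelse(ppi & cox, "both", ifelse(ppi, "ppi", "coexpr"))
  edges <- data.frame(gene_a = el[, 1], gene_b = el[, 2],
                      support = support, stringsAsFactors = FALSE)
  nodes <- data.frame(
    gene = igraph::V(network)$name %||% character(),
    role = V_attr(network, "role", "none"),
    regulation = V_attr(network, "regulation", "none"),
    stringsAsFactors = FALSE
  )
  write_table(edges, paste0(path, ".edges.tsv"))
  write_table(nodes, paste0(path, ".nodes.tsv"))
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  edges <- utils::read.delim(paste0(path, ".edges.tsv"), sep = "\t",
                             stringsAsFactors = FALSE)
  nodes <- utils::read.delim(paste0(path, ".nodes.tsv"), sep = "\t",
                             stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b"), drop = FALSE],
    directed = FALSE,
    vertices = nodes[, "gene", drop = FALSE]
  )
  if (nrow(edges)) {
    igraph::E(g)$ppi <- edges$support %in% c("ppi", "both")
    igraph::E(g)$coexpr <- edges$support %in% c("coexpr", "both")
  }
  igraph::V(g)$role <- nodes$role
  igraph::V(g)$regulation <- nodes$regulation
  g
}

#' Write a data frame as a TSV table
#'
#' @param rows A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Attribute accessors tolerant of missing attributes (filled with a default).
E_attr <- function(g, name, default) {
  v <- igraph::edge_attr(g, name)
  if (is.null(v)) rep(default, igraph::ecount(g)) else v
}
V_attr <- function(g, name, default) {
  v <- igraph::vertex_attr(g, name)
  if (is.null(v)) rep(default, igraph::vcount(g)) else v
}
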