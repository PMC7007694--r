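#' Construct a named seed gene set
#'
#' A `gene_set` is the unit seed list of the pipeline: differentially
#' expressed genes (with up/down regulation labels) or disease/function
#' candidate lists (ASD, epilepsy, learning/memory). Symbols are stored
#' unique, in first-seen order.
#'
#' @param genes Character vector of gene symbols.
#' @param regulation Optional character vector parallel to `genes` with values
#'   in `"up"`, `"down"`, `"none"`, or a named vector (names = genes).
#' @param name Label for the set (e.g. `"deg"`, `"asd"`).
#' @param normalize Normalize symbols via [normalize_symbol()] (default TRUE).
#' @return An object of class `gene_set`: a list with elements `name`,
#'   `genes` (unique character) and `regulation` (named character, one of
#'   up/down/none per gene).
#' @export
gene_set <- function(genes, regulation = NULL, name = "geneset",
                     normalize = TRUE) {
  genes <- as.character(genes)
  if (normalize) genes <- normalize_symbol(genes)
  if (any(!nzchar(genes) | is.na(genes))) {
    stop_fmt("gene_set '%s': empty or missing gene symbols are not allowed", name)
  }
  reg <- NULL
  if (!is.null(regulation)) {
    if (is.null(names(regulation))) {
      if (length(regulation) != length(genes)) {
        stop_fmt("regulation must be named or match length of genes")
      }
      names(regulation) <- genes
    } else if (normalize) {
      names(regulation) <- normalize_symbol(names(regulation))
    }
    bad <- setdiff(unique(regulation), c("up", "down", "none"))
    if (length(bad)) stop_fmt("unknown regulation label(s): %s",
                              paste(bad, collapse = ", "))
    # one label per gene; conflicting labels are a data error
    tab <- tapply(unname(regulation), names(regulation),
                  function(v) length(unique(v)))
    conflict <- names(tab)[tab > 1L]
    if (length(conflict)) {
      stop_fmt("conflicting regulation labels for gene(s): %s",
               paste(conflict, collapse = ", "))
    }
    reg <- regulation[!duplicated(names(regulation))]
  }
  ug <- unique(genes)
  full <- rep("none", length(ug))
  names(full) <- ug
  if (!is.null(reg)) full[intersect(names(reg), ug)] <- reg[intersect(names(reg), ug)]
  structure(list(name = name, genes = ug, regulation = full),
            class = "gene_set")
}

#' @export
length.gene_set <- function(x) length(x$genes)

#' @export
print.gene_set <- function(x, ...) {
  n_up <- sum(x$regulation == "up")
  n_dn <- sum(x$regulation == "down")
  cat(sprintf("<gene_set '%s'> %d genes", x$name, length(x$genes)))
  if (n_up + n_dn > 0) cat(sprintf(" (%d up, %d down)", n_up, n_dn))
  cat("\n")
  invisible(x)
}

# Coerce character vectors / gene_set to a plain symbol vector. Symbols are
# normalized by the parsers, so joins are exact-match by default.
as_genes <- function(x, normalize = FALSE) {
  if (inherits(x, "gene_set")) return(x$genes)
  g <- as.character(x)
  if (normalize) g <- normalize_symbol(g)
  unique(g)
}
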