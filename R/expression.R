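#' Expression matrix container
#'
#' Holds a genes x samples experiment with two groups of samples. At least one
#' of `counts` (non-negative integers) or `fpkm` (non-negative reals) must be
#' present; gene lengths (bp) are needed to derive FPKM from counts.
#'
#' @param counts Optional genes x samples integer matrix with rownames = gene
#'   symbols.
#' @param fpkm Optional genes x samples numeric matrix.
#' @param gene_lengths Optional named numeric vector of transcript lengths (bp).
#' @param groups Character vector of group labels, one per sample column.
#' @return An object of class `expression_matrix` with elements `genes`,
#'   `samples` (data frame with `sample`, `group`), `counts`, `fpkm`,
#'   `gene_lengths`.
#' @export
expression_matrix <- function(counts = NULL, fpkm = NULL, gene_lengths = NULL,
                              groups) {
  if (is.null(counts) && is.null(fpkm)) {
    stop_fmt("expression_matrix: at least one of counts/fpkm must be supplied")
  }
  ref <- counts %||% fpkm
  genes <- rownames(ref)
  if (is.null(genes)) stop_fmt("expression_matrix: matrices must have gene rownames")
  if (anyDuplicated(genes)) stop_fmt("expression_matrix: duplicate gene symbols")
  ns <- ncol(ref)
  if (length(groups) != ns) {
    stop_fmt("expression_matrix: %d group labels for %d samples", length(groups), ns)
  }
  for (m in list(counts, fpkm)) {
    if (!is.null(m) && (!identical(rownames(m), genes) || ncol(m) != ns)) {
      stop_fmt("expression_matrix: counts/fpkm dimensions or gene order differ")
    }
  }
  if (!is.null(counts) && any(counts < 0)) stop_fmt("negative counts")
  if (!is.null(gene_lengths)) {
    gene_lengths <- gene_lengths[genes]
    if (anyNA(gene_lengths)) stop_fmt("gene_lengths missing for some genes")
  }
  ids <- colnames(ref) %||% paste0("s", seq_len(ns))
  structure(list(
    genes = genes,
    samples = data.frame(sample = ids, group = as.character(groups),
                         stringsAsFactors = FALSE),
    counts = counts, fpkm = fpkm, gene_lengths = gene_lengths
  ), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples (%s)%s%s\n",
              length(x$genes), nrow(x$samples),
              paste(table(x$samples$group), collapse = "+"),
              if (!is.null(x$counts)) " counts" else "",
              if (!is.null(x$fpkm)) " fpkm" else ""))
  invisible(x)
}

#' Read / write an expression matrix TSV
#'
#' Plain TSV dialect: first column `gene`, remaining columns one per sample.
#'
#' @param path File path.
#' @param groups Group labels, one per sample column (read only).
#' @param what Which slot to write: `"counts"` or `"fpkm"`.
#' @param mat For writing, an `expression_matrix`.
#' @return `read_expression_matrix()` returns an [expression_matrix()] with
#'   the chosen slot filled.
#' @export
read_expression_matrix <- function(path, groups, what = c("counts", "fpkm")) {
  what <- match.arg(what)
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- normalize_symbol(df[[1L]])
  if (what == "counts") {
    expression_matrix(counts = m, groups = groups)
  } else {
    expression_matrix(fpkm = m, groups = groups)
  }
}

#' @rdname read_expression_matrix
#' @export
write_expression_matrix <- function(mat, path, what = c("counts", "fpkm")) {
  what <- match.arg(what)
  m <- mat[[what]]
  if (is.null(m)) stop_fmt("expression matrix has no '%s' slot", what)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table(df, path)
}

#' Expressed-gene filter
#'
#' A gene counts as expressed when it has strictly more than `min_count` raw
#' counts in at least `min_samples` samples. The resulting set is the
#' expressed-gene universe used by all downstream network stages.
#'
#' @param mat An [expression_matrix()] with counts.
#' @param min_count Count threshold (strict inequality; default 1).
#' @param min_samples Minimum number of qualifying samples (default 4).
#' @return A [gene_set()] named `"expressed"`.
#' @export
filter_expressed <- function(mat, min_count = 1, min_samples = 4) {
  if (is.null(mat$counts)) {
    stop_fmt(paste0("filter_expressed needs raw counts; supply counts or ",
                    "provide an explicit expressed-gene universe list"))
  }
  keep <- rowSums(mat$counts > min_count) >= min_samples
  gene_set(rownames(mat$counts)[keep], name = "expressed", normalize = FALSE)
}

#' FPKM from raw counts
#'
#' `fpkm = count * 1e9 / (library_size * length)` — fragments per kilobase of
#' transcript per million mapped reads.
#'
#' @param counts Genes x samples count matrix (gene rownames).
#' @param gene_lengths Named numeric vector of transcript lengths in bp.
#' @param library_sizes Per-sample totals; defaults to column sums of `counts`.
#' @return Numeric matrix of FPKM values, same shape as `counts`.
#' @export
compute_fpkm <- function(counts, gene_lengths,
                         library_sizes = colSums(counts)) {
  gl <- gene_lengths[rownames(counts)]
  if (anyNA(gl)) {
    stop_fmt("compute_fpkm: missing length for gene(s): %s",
             paste(utils::head(rownames(counts)[is.na(gl)], 5), collapse = ", "))
  }
  if (any(gl <= 0)) {
    stop_fmt("compute_fpkm: non-positive length for gene(s): %s",
             paste(utils::head(rownames(counts)[gl <= 0], 5), collapse = ", "))
  }
  if (any(library_sizes <= 0)) stop_fmt("compute_fpkm: non-positive library size")
  sweep(counts / gl, 2, library_sizes, "/") * 1e9
}

#' Co-expression edges at a hard Pearson cutoff
#'
#' Computes pairwise Pearson correlation of FPKM profiles over all samples
#' (both groups pooled) and keeps pairs passing the cutoff: `|r| >= cutoff`
#' under `mode = "absolute"` (default) or `r >= cutoff` under
#' `mode = "signed"`. Constant-profile genes have undefined correlation and
#' contribute no edges (a message reports how many were skipped).
#'
#' @param mat An [expression_matrix()]; FPKM is used if present, otherwise it
#'   is derived from counts and gene lengths.
#' @param cutoff Correlation cutoff in `[0, 1]` (default 0.75).
#' @param mode `"absolute"` or `"signed"`.
#' @param genes Optional restriction of the gene universe (e.g. the expressed
#'   set); a [gene_set()] or character vector.
#' @param log_transform Correlate `log2(FPKM + 1)` instead of raw FPKM
#'   (default FALSE).
#' @return An object of class `coexpression_edges`: data frame with columns
#'   `gene_a`, `gene_b`, `r` (one row per kept unordered pair, `gene_a <
#'   gene_b`), with attributes `cutoff` and `mode`.
#' @export
coexpression_edges <- function(mat, cutoff = 0.75,
                               mode = c("absolute", "signed"),
                               genes = NULL, log_transform = FALSE) {
  mode <- match.arg(mode)
  x <- mat$fpkm
  if (is.null(x)) {
    if (is.null(mat$counts) || is.null(mat$gene_lengths)) {
      stop_fmt("coexpression_edges: FPKM absent and cannot be derived")
    }
    x <- compute_fpkm(mat$counts, mat$gene_lengths)
  }
  if (ncol(x) < 3L) {
    stop_fmt("coexpression_edges: need >= 3 samples, got %d", ncol(x))
  }
  if (!is.null(genes)) {
    keep <- intersect(rownames(x), as_genes(genes))
    x <- x[keep, , drop = FALSE]
  }
  if (log_transform) x <- log2(x + 1)
  sds <- apply(x, 1, stats::sd)
  n_const <- sum(sds == 0 | is.na(sds))
  if (n_const > 0) {
    message(sprintf("coexpression_edges: %d constant-profile gene(s) skipped",
                    n_const))
    x <- x[sds > 0 & !is.na(sds), , drop = FALSE]
  }
  ng <- nrow(x)
  if (ng < 2L) {
    out <- data.frame(gene_a = character(), gene_b = character(),
                      r = numeric(), stringsAsFactors = FALSE)
  } else {
    cm <- stats::cor(t(x))
    idx <- which(upper.tri(cm), arr.ind = TRUE)
    r <- cm[idx]
    pass <- if (mode == "absolute") abs(r) >= cutoff else r >= cutoff
    pass[is.na(pass)] <- FALSE
    out <- data.frame(gene_a = rownames(x)[idx[pass, 1L]],
                      gene_b = rownames(x)[idx[pass, 2L]],
                      r = r[pass], stringsAsFactors = FALSE)
    swap <- out$gene_a > out$gene_b
    tmp <- out$gene_a[swap]
    out$gene_a[swap] <- out$gene_b[swap]
    out$gene_b[swap] <- tmp
    out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "cutoff") <- cutoff
  attr(out, "mode") <- mode
  class(out) <- c("coexpression_edges", class(out))
  out
}
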