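#' Configuration of the synthetic-data generator
#'
#' Describes the simulated world every downstream stage is tested on: a
#' scale-free (or Erdos-Renyi) PPI graph; a negative-binomial count matrix for
#' two groups of samples with Gaussian-copula co-expression blocks and planted
#' differential expression; disease/function seed sets with a planted
#' enrichment odds ratio for DEG membership; and pathway annotations with
#' planted over-represented pathways. Defaults mirror the motivating study
#' design (3 + 3 samples; 15,254-gene universe with 1,247 DEGs and seed sets
#' of 876/496/585, scaled down ~7.6x to desk scale; PPI mean degree
#' 2 * 9205 / 4202).
#'
#' @param n_genes Number of genes in the universe (default 2000).
#' @param n_samples_per_group Samples per group (default 3).
#' @param ppi_model `"scale_free"` (preferential attachment) or
#'   `"erdos_renyi"` with `n * k / 2` edges.
#' @param ppi_mean_degree Target mean degree (default 4.4).
#' @param n_coexpr_blocks,block_size Number and size of co-expression blocks;
#'   block genes follow the planted DEGs in gene order.
#' @param within_block_correlation Latent-factor correlation within a block,
#'   in `[0, 1]` (default 0.9).
#' @param n_deg Number of planted differentially expressed genes (the first
#'   `n_deg` genes; default 160).
#' @param deg_up_fraction Fraction of planted DEGs that are upregulated
#'   (default 787/1247).
#' @param lfc_mean Absolute log2 fold change of planted DEGs (default 1.5).
#' @param dispersion Negative-binomial dispersion (size = 1/dispersion;
#'   default 0.1).
#' @param seed_set_sizes Named integer vector of seed-set sizes (default
#'   `c(asd = 115, ep = 65, lm = 77)`).
#' @param planted_enrichment_odds Odds of seed membership for DEGs vs
#'   non-DEGs (>= 1; `Inf` draws seeds from DEGs only; default 3).
#' @param n_pathways Number of pathways (default 60).
#' @param pathway_size_range Size range of non-planted pathways (default
#'   `c(20, 80)`).
#' @param planted_enriched_pathways Number of planted over-represented
#'   pathways (default 3), each of `planted_pathway_size` genes of which
#'   `planted_seed_members` are drawn from a seed set (defaults 30 and 25
#'   target a hypergeometric tail far below 1e-6 with >= 10 hits).
#' @param planted_pathway_size,planted_seed_members See above.
#' @param rng_seed Master seed; each generator uses a derived stream, so
#'   identical configs give byte-identical outputs.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_samples_per_group = 3,
                       ppi_model = c("scale_free", "erdos_renyi"),
                       ppi_mean_degree = 4.4,
                       n_coexpr_blocks = 10,
                       block_size = 20,
                       within_block_correlation = 0.9,
                       n_deg = 160,
                       deg_up_fraction = 787 / 1247,
                       lfc_mean = 1.5,
                       dispersion = 0.1,
                       seed_set_sizes = c(asd = 115, ep = 65, lm = 77),
                       planted_enrichment_odds = 3,
                       n_pathways = 60,
                       pathway_size_range = c(20, 80),
                       planted_enriched_pathways = 3,
                       planted_pathway_size = 30,
                       planted_seed_members = 25,
                       rng_seed = 1) {
  ppi_model <- match.arg(ppi_model)
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_samples_per_group = as.integer(n_samples_per_group),
    ppi_model = ppi_model,
    ppi_mean_degree = ppi_mean_degree,
    n_coexpr_blocks = as.integer(n_coexpr_blocks),
    block_size = as.integer(block_size),
    within_block_correlation = within_block_correlation,
    n_deg = as.integer(n_deg),
    deg_up_fraction = deg_up_fraction,
    lfc_mean = lfc_mean,
    dispersion = dispersion,
    seed_set_sizes = seed_set_sizes,
    planted_enrichment_odds = planted_enrichment_odds,
    n_pathways = as.integer(n_pathways),
    pathway_size_range = as.integer(pathway_size_range),
    planted_enriched_pathways = as.integer(planted_enriched_pathways),
    planted_pathway_size = as.integer(planted_pathway_size),
    planted_seed_members = as.integer(planted_seed_members),
    rng_seed = as.integer(rng_seed)
  )
  with(cfg, {
    if (n_genes < 10) stop_fmt("sim_config: n_genes must be >= 10")
    if (n_samples_per_group < 1) stop_fmt("sim_config: need >= 1 sample per group")
    if (ppi_mean_degree >= n_genes) {
      stop_fmt("sim_config: mean degree %g >= n_genes %d", ppi_mean_degree, n_genes)
    }
    if (within_block_correlation < 0 || within_block_correlation > 1) {
      stop_fmt("sim_config: within_block_correlation must be in [0, 1]")
    }
    if (n_deg < 0 || n_deg > n_genes) stop_fmt("sim_config: invalid n_deg")
    if (n_deg + n_coexpr_blocks * block_size > n_genes) {
      stop_fmt("sim_config: DEGs plus co-expression blocks exceed n_genes")
    }
    if (is.null(names(seed_set_sizes)) || any(seed_set_sizes < 1)) {
      stop_fmt("sim_config: seed_set_sizes must be a named vector of positive counts")
    }
    if (any(seed_set_sizes > n_genes)) {
      stop_fmt("sim_config: requested seed-set size exceeds the gene universe")
    }
    if (planted_enrichment_odds < 1) {
      stop_fmt("sim_config: planted_enrichment_odds must be >= 1")
    }
    if (length(pathway_size_range) != 2 ||
        pathway_size_range[1] > pathway_size_range[2] ||
        pathway_size_range[2] > n_genes) {
      stop_fmt("sim_config: infeasible pathway_size_range")
    }
    if (planted_seed_members > planted_pathway_size ||
        planted_pathway_size > n_genes) {
      stop_fmt("sim_config: infeasible planted pathway sizes")
    }
    if (dispersion <= 0) stop_fmt("sim_config: dispersion must be > 0")
  })
  structure(cfg, class = "sim_config")
}

sim_gene_ids <- function(n) {
  sprintf("G%0*d", max(4L, nchar(as.character(n))), seq_len(n))
}

#' Simulate a PPI edge list
#'
#' Scale-free graphs come from undirected preferential attachment with
#' `m = round(mean_degree / 2)` edges per arriving vertex (heavy-tailed degree
#' distribution); Erdos-Renyi graphs have exactly `round(n * k / 2)` edges.
#' The result is a simple graph (no self-loops, no multi-edges) over the
#' synthetic symbols `G0001`, `G0002`, ...
#'
#' @param config A [sim_config()].
#' @return A data frame of edge records (`gene_a`, `gene_b`, `source_tag`),
#'   as produced by [read_edge_list()].
#' @export
simulate_ppi <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  ids <- sim_gene_ids(n)
  g <- with_seed(config$rng_seed + 101L, {
    if (config$ppi_model == "scale_free") {
      m <- max(1L, round(config$ppi_mean_degree / 2))
      igraph::sample_pa(n, m = m, directed = FALSE)
    } else {
      igraph::sample_gnm(n, round(n * config$ppi_mean_degree / 2))
    }
  })
  g <- igraph::simplify(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  data.frame(gene_a = ids[el[, 1L]], gene_b = ids[el[, 2L]],
             source_tag = "simulated", stringsAsFactors = FALSE)
}

#' Simulate a count + FPKM expression matrix
#'
#' Counts follow a negative-binomial model with lognormal gene-level means.
#' Co-expression blocks are induced through a Gaussian copula: genes of block
#' `b` share a per-sample latent factor with loading
#' `sqrt(within_block_correlation)`, and counts are the NB quantile transform
#' of the latent normal score — the simplest construction that preserves both
#' the count nature of RNA-seq and a tunable Pearson correlation. The first
#' `n_deg` genes receive a group-2 mean shift of `2^lfc_mean` (up) or
#' `2^-lfc_mean` (down). FPKM is derived from the counts with fixed synthetic
#' gene lengths (uniform 500-5000 bp) and realized library sizes.
#'
#' @param config A [sim_config()].
#' @return An [expression_matrix()] with counts, FPKM, gene lengths and group
#'   labels; the planted DEG list (a [gene_set()] with up/down labels) is
#'   attached as attribute `"planted_deg"`, block assignments as `"block"`.
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  ns <- 2L * config$n_samples_per_group
  ids <- sim_gene_ids(n)
  groups <- rep(c("wt", "ko"), each = config$n_samples_per_group)
  block <- rep(0L, n)
  nb <- config$n_coexpr_blocks
  bs <- config$block_size
  if (nb > 0 && bs > 0) {
    block[config$n_deg + seq_len(nb * bs)] <- rep(seq_len(nb), each = bs)
  }
  n_up <- round(config$n_deg * config$deg_up_fraction)
  direction <- rep("none", n)
  if (config$n_deg > 0) {
    direction[seq_len(config$n_deg)] <- c(rep("up", n_up),
                                          rep("down", config$n_deg - n_up))
  }
  rho <- config$within_block_correlation
  size <- 1 / config$dispersion
  res <- with_seed(config$rng_seed + 202L, {
    mu <- stats::rlnorm(n, meanlog = log(50), sdlog = 1.3)
    lengths_bp <- round(stats::runif(n, 500, 5000))
    f <- matrix(stats::rnorm(nb * ns), nb, ns)        # block latent factors
    eps <- matrix(stats::rnorm(n * ns), n, ns)
    z <- eps
    in_block <- block > 0L
    if (any(in_block)) {
      z[in_block, ] <- sqrt(rho) * f[block[in_block], , drop = FALSE] +
        sqrt(1 - rho) * eps[in_block, , drop = FALSE]
    }
    fc <- matrix(1, n, ns)
    ko <- groups == "ko"
    fc[direction == "up", ko] <- 2^config$lfc_mean
    fc[direction == "down", ko] <- 2^(-config$lfc_mean)
    u <- stats::pnorm(z)
    # clamp away from 1 so qnbinom stays finite
    u <- pmin(u, 1 - 1e-12)
    counts <- matrix(stats::qnbinom(u, size = size, mu = mu * fc), n, ns)
    list(counts = counts, mu = mu, lengths_bp = lengths_bp)
  })
  counts <- res$counts
  rownames(counts) <- ids
  colnames(counts) <- paste0(groups, rep(seq_len(config$n_samples_per_group), 2))
  lengths_bp <- res$lengths_bp
  names(lengths_bp) <- ids
  # nominal (constant) library size: at desk-scale gene counts the realized
  # column sums are dominated by the genes themselves, and normalizing by
  # them would cancel shared block variation (a compositional artifact real
  # 15k-gene libraries do not show)
  fpkm <- compute_fpkm(counts, lengths_bp, library_sizes = rep(1e6, ns))
  mat <- expression_matrix(counts = counts, fpkm = fpkm,
                           gene_lengths = lengths_bp, groups = groups)
  deg_idx <- which(direction != "none")
  attr(mat, "planted_deg") <- gene_set(ids[deg_idx],
                                       regulation = direction[deg_idx],
                                       name = "deg", normalize = FALSE)
  attr(mat, "block") <- stats::setNames(block, ids)
  mat
}

#' Planted DEG list of a configuration
#'
#' @param config A [sim_config()].
#' @return The planted DEG [gene_set()] (determined by the config alone).
#' @export
planted_deg_set <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ids <- sim_gene_ids(config$n_genes)
  n_up <- round(config$n_deg * config$deg_up_fraction)
  direction <- c(rep("up", n_up), rep("down", config$n_deg - n_up))
  gene_set(ids[seq_len(config$n_deg)], regulation = direction, name = "deg",
           normalize = FALSE)
}

# Density of Fisher's noncentral hypergeometric distribution: the number of
# "successes" (DEGs) among a fixed-size draw when each DEG's membership odds
# are psi times a non-DEG's. Used so the planted odds ratio is exactly the
# conditional odds ratio of the generated seed sets.
nchg_density <- function(n_draw, n_deg, n_other, psi) {
  lo <- max(0L, n_draw - n_other)
  hi <- min(n_draw, n_deg)
  k <- lo:hi
  logw <- lchoose(n_deg, k) + lchoose(n_other, n_draw - k) + k * log(psi)
  w <- exp(logw - max(logw))
  list(k = k, p = w / sum(w))
}

#' Simulate seed gene sets with planted DEG enrichment
#'
#' Each seed set is drawn so that the odds of membership for a DEG versus a
#' non-DEG equal `planted_enrichment_odds`: the DEG-overlap count comes from
#' Fisher's noncentral hypergeometric distribution with that odds parameter,
#' then genes are sampled uniformly within the DEG and non-DEG strata.
#' `planted_enrichment_odds = Inf` draws the whole set from the DEGs.
#'
#' @param config A [sim_config()].
#' @param deg_list The DEG [gene_set()] (e.g. from [simulate_expression()]'s
#'   `"planted_deg"` attribute); must be a subset of the gene universe.
#' @return Named list of [gene_set()]s, one per entry of
#'   `config$seed_set_sizes`.
#' @export
simulate_seed_sets <- function(config, deg_list) {
  stopifnot(inherits(config, "sim_config"))
  ids <- sim_gene_ids(config$n_genes)
  deg <- as_genes(deg_list)
  if (!all(deg %in% ids)) stop_fmt("simulate_seed_sets: DEG list outside universe")
  other <- setdiff(ids, deg)
  psi <- config$planted_enrichment_odds
  sizes <- config$seed_set_sizes
  out <- vector("list", length(sizes))
  names(out) <- names(sizes)
  for (i in seq_along(sizes)) {
    sz <- sizes[[i]]
    if (sz > length(ids)) stop_fmt("seed set '%s' larger than universe", names(sizes)[i])
    genes <- with_seed(config$rng_seed + 303L + i, {
      if (is.infinite(psi)) {
        if (sz > length(deg)) stop_fmt("odds = Inf but seed set exceeds DEG count")
        sample(deg, sz)
      } else {
        dens <- nchg_density(sz, length(deg), length(other), psi)
        k <- sample(dens$k, 1L, prob = dens$p)
        c(sample(deg, k), sample(other, sz - k))
      }
    })
    out[[i]] <- gene_set(genes, name = names(sizes)[i], normalize = FALSE)
  }
  out
}

#' Simulate pathway annotations with planted enriched pathways
#'
#' Planted pathways take `planted_seed_members` genes from a seed set (cycling
#' over the supplied sets) and the remainder uniformly from the rest of the
#' universe; at the default sizes this targets a one-sided hypergeometric
#' over-representation tail far below `1e-6` with at least 10 seed hits.
#' The remaining pathways sample genes uniformly.
#'
#' @param config A [sim_config()].
#' @param seed_sets Named list of [gene_set()]s (from [simulate_seed_sets()]).
#' @return A `gmt` object; planted pathway ids are
#'   `"PLANTED01_<seedset>"`, ..., the rest `"P0001"`, ...
#' @export
simulate_pathways <- function(config, seed_sets) {
  stopifnot(inherits(config, "sim_config"))
  ids <- sim_gene_ids(config$n_genes)
  n_planted <- config$planted_enriched_pathways
  n_null <- config$n_pathways - n_planted
  if (n_null < 0) stop_fmt("more planted pathways than n_pathways")
  recs <- vector("list", config$n_pathways)
  with_seed(config$rng_seed + 404L, {
    for (i in seq_len(n_planted)) {
      ss <- seed_sets[[((i - 1L) %% length(seed_sets)) + 1L]]
      hits <- sample(ss$genes, config$planted_seed_members)
      rest <- sample(setdiff(ids, ss$genes),
                     config$planted_pathway_size - config$planted_seed_members)
      recs[[i]] <- list(
        pathway_id = sprintf("PLANTED%02d_%s", i, ss$name),
        description = sprintf("planted enriched pathway (%s)", ss$name),
        members = sample(c(hits, rest))
      )
    }
    for (j in seq_len(n_null)) {
      sz <- sample(config$pathway_size_range[1]:config$pathway_size_range[2], 1L)
      recs[[n_planted + j]] <- list(
        pathway_id = sprintf("P%04d", j),
        description = "background pathway",
        members = sample(ids, sz)
      )
    }
  })
  structure(recs, class = "gmt")
}

#' Generate one complete synthetic input bundle
#'
#' Runs every generator under the config's master seed and (optionally) writes
#' the external-file forms the readers consume.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory; when given, writes `ppi.tsv`,
#'   `counts.tsv`, `fpkm.tsv`, `gene_lengths.tsv`, `deg.tsv`,
#'   `<seedset>.txt` lists and `pathways.gmt`.
#' @return List with `config`, `ppi`, `expression`, `deg`, `seed_sets`,
#'   `pathways`.
#' @export
simulate_all <- function(config = sim_config(), dir = NULL) {
  ppi <- simulate_ppi(config)
  expr <- simulate_expression(config)
  deg <- attr(expr, "planted_deg")
  seed_sets <- simulate_seed_sets(config, deg)
  pathways <- simulate_pathways(config, seed_sets)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_table(ppi, file.path(dir, "ppi.tsv"))
    write_expression_matrix(expr, file.path(dir, "counts.tsv"), "counts")
    write_expression_matrix(expr, file.path(dir, "fpkm.tsv"), "fpkm")
    write_table(data.frame(gene = names(expr$gene_lengths),
                           length_bp = unname(expr$gene_lengths)),
                file.path(dir, "gene_lengths.tsv"))
    writeLines(paste(deg$genes, deg$regulation[deg$genes], sep = "\t"),
               file.path(dir, "deg.tsv"))
    for (nm in names(seed_sets)) {
      writeLines(seed_sets[[nm]]$genes, file.path(dir, paste0(nm, ".txt")))
    }
    write_gmt(pathways, file.path(dir, "pathways.gmt"))
  }
  list(config = config, ppi = ppi, expression = expr, deg = deg,
       seed_sets = seed_sets, pathways = pathways)
}
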