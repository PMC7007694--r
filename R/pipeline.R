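#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis. With
#' `synthetic = TRUE` (the default) all inputs come from [simulate_all()];
#' otherwise the `paths` entries must point at existing input files.
#'
#' @param out_dir Output directory for artifacts and the run manifest.
#' @param rng_seed Master seed fanned out to every stochastic stage.
#' @param synthetic Generate inputs with [simulate_all()]?
#' @param sim Simulation configuration ([sim_config()]); its `rng_seed` is
#'   overridden by `rng_seed`.
#' @param coexpr_cutoff,coexpr_mode Co-expression threshold and sign handling
#'   (see [coexpression_edges()]).
#' @param null_reps Node-shuffle replicates per seed set (default 1000).
#' @param bootstrap_B Bootstrap resamples for enrichment SEs (default 100).
#' @param pathway_p_cut,pathway_min_hits Bipartite keep thresholds (defaults
#'   `1e-6` and 10).
#' @param paths Named list of input file paths (used when
#'   `synthetic = FALSE`): `ppi`, `counts`, `fpkm`, `gene_lengths`, `deg`,
#'   seed lists, `gmt`, plus `groups` (character vector of group labels).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("netconverge_run_"),
                            rng_seed = 1,
                            synthetic = TRUE,
                            sim = sim_config(rng_seed = rng_seed),
                            coexpr_cutoff = 0.75,
                            coexpr_mode = "absolute",
                            null_reps = 1000,
                            bootstrap_B = 100,
                            pathway_p_cut = 1e-6,
                            pathway_min_hits = 10,
                            paths = list()) {
  stopifnot(coexpr_cutoff >= 0, coexpr_cutoff <= 1, null_reps >= 1,
            bootstrap_B >= 1, pathway_p_cut > 0, pathway_min_hits >= 0)
  sim$rng_seed <- as.integer(rng_seed)
  structure(list(
    out_dir = out_dir, rng_seed = as.integer(rng_seed), synthetic = synthetic,
    sim = sim, coexpr_cutoff = coexpr_cutoff, coexpr_mode = coexpr_mode,
    null_reps = as.integer(null_reps), bootstrap_B = as.integer(bootstrap_B),
    pathway_p_cut = pathway_p_cut,
    pathway_min_hits = as.integer(pathway_min_hits),
    paths = paths
  ), class = "pipeline_config")
}

load_pipeline_inputs <- function(config) {
  if (config$synthetic) {
    sim <- simulate_all(config$sim)
    list(ppi = sim$ppi, expression = sim$expression, deg = sim$deg,
         seed_sets = sim$seed_sets, pathways = sim$pathways)
  } else {
    p <- config$paths
    need <- c("ppi", "counts", "gene_lengths", "deg", "gmt", "groups")
    miss <- setdiff(need, names(p))
    if (length(miss)) stop_fmt("pipeline paths missing: %s",
                               paste(miss, collapse = ", "))
    expr <- read_expression_matrix(p$counts, groups = p$groups, what = "counts")
    gl <- utils::read.delim(p$gene_lengths, stringsAsFactors = FALSE)
    lengths_bp <- stats::setNames(gl[[2L]], normalize_symbol(gl[[1L]]))
    fpkm <- compute_fpkm(expr$counts, lengths_bp)
    expr <- expression_matrix(counts = expr$counts, fpkm = fpkm,
                              gene_lengths = lengths_bp,
                              groups = expr$samples$group)
    seed_names <- setdiff(names(p), need)
    seed_sets <- lapply(seed_names, function(nm) read_gene_list(p[[nm]], name = nm))
    names(seed_sets) <- seed_names
    list(ppi = read_edge_list(p$ppi), expression = expr,
         deg = read_gene_list(p$deg, name = "deg"),
         seed_sets = seed_sets, pathways = read_gmt(p$gmt))
  }
}

#' Run the full network-convergence analysis
#'
#' Sequences the stages: expressed-gene filter, co-expression edges, tissue
#' interactome with co-expression annotation, seed subnetworks (DEG plus each
#' seed set), node-shuffle nulls, the enrichment panel over nested universes
#' (expressed ⊃ DEG ⊃ DEG-subnetwork nodes), gene-pathway bipartite
#' subnetworks, converged PPI and pathway modules, and PPI-vs-bipartite
#' pathway-list overlaps. Every artifact is written under `config$out_dir`
#' along with a manifest (input hashes, seed, stage log).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list bundle of all stage results (also written to
#'   disk).
#' @export
run_all <- function(config = pipeline_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character()
  t0 <- Sys.time()
  stage <- function(name, code) {
    ts <- Sys.time()
    res <- tryCatch(force(code), error = function(e) {
      stop_fmt("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    stages[[length(stages) + 1L]] <<- sprintf("%s\t%.2fs", name,
                                              as.numeric(Sys.time() - ts, "secs"))
    res
  }

  inputs <- stage("inputs", load_pipeline_inputs(config))
  expressed <- stage("filter_expressed", filter_expressed(inputs$expression))
  coexpr <- stage("coexpression", coexpression_edges(
    inputs$expression, cutoff = config$coexpr_cutoff,
    mode = config$coexpr_mode, genes = expressed))
  interactome <- stage("interactome", {
    net <- build_tissue_interactome(inputs$ppi, expressed)
    annotate_coexpression(net, coexpr)
  })

  all_seed_sets <- c(list(deg = inputs$deg), inputs$seed_sets)
  subnets <- stage("subnetworks", lapply(all_seed_sets, function(s) {
    extract_seed_subnetwork(interactome, s)
  }))
  nulls <- stage("nulls", {
    out <- vector("list", length(all_seed_sets))
    names(out) <- names(all_seed_sets)
    for (i in seq_along(all_seed_sets)) {
      out[[i]] <- shuffle_null(interactome, all_seed_sets[[i]],
                               reps = config$null_reps,
                               rng_seed = config$rng_seed + 1000L * i)
    }
    out
  })

  deg_subnet_nodes <- igraph::V(subnets$deg)$name %||% character()
  # the DEG universe is the expressed DEGs, mirroring DEG calls made within
  # the expressed-gene universe; subnetwork nodes include non-DEG neighbors
  # and are compared non-nested by the panel
  universes <- list(expressed = expressed,
                    deg = intersect(as_genes(inputs$deg), expressed$genes),
                    deg_subnetwork = deg_subnet_nodes)
  universes <- universes[lengths(lapply(universes, as_genes)) > 0]
  panel <- stage("enrichment_panel", enrichment_panel(
    inputs$seed_sets, universes = universes,
    B = config$bootstrap_B, rng_seed = config$rng_seed + 5000L))

  bip <- stage("bipartite", build_bipartite(inputs$pathways, expressed))
  bip_rows <- stage("pathway_enrichment", lapply(all_seed_sets, function(s) {
    suppressWarnings(pathway_enrichment(bip, s, p_cut = config$pathway_p_cut,
                                        min_hits = config$pathway_min_hits))
  }))
  bip_subnets <- stage("bipartite_subnetworks", {
    out <- vector("list", length(all_seed_sets))
    names(out) <- names(all_seed_sets)
    for (nm in names(all_seed_sets)) {
      out[[nm]] <- bipartite_subnetwork(bip, bip_rows[[nm]], all_seed_sets[[nm]])
    }
    out
  })

  conv_names <- setdiff(names(inputs$seed_sets), "deg")
  converged_ppi <- NULL
  converged_pathways <- NULL
  if (length(conv_names) >= 2L) {
    converged_ppi <- stage("converged_module",
                           converged_module(subnets[conv_names], interactome))
    converged_pathways <- stage("converged_pathway_module",
                                converged_pathway_module(bip_subnets[conv_names]))
  }

  overlaps <- stage("pathway_overlap", {
    rows <- list()
    for (nm in names(all_seed_sets)) {
      bip_kept <- bip_rows[[nm]]$pathway_id[bip_rows[[nm]]$kept]
      ppi_nodes <- igraph::V(subnets[[nm]])$name %||% character()
      ppi_rows <- suppressWarnings(pathway_enrichment(
        bip, ppi_nodes, p_cut = config$pathway_p_cut,
        min_hits = config$pathway_min_hits))
      ppi_kept <- ppi_rows$pathway_id[ppi_rows$kept]
      ov <- if (length(bip_kept)) pathway_list_overlap(bip_kept, ppi_kept) else
        list(n_a = 0L, n_overlap = 0L, percent = NA_real_)
      rows[[nm]] <- data.frame(seed_set = nm, n_bipartite = ov$n_a,
                               n_shared_with_ppi = ov$n_overlap,
                               percent = ov$percent, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })

  stage("write_artifacts", {
    od <- config$out_dir
    write_network(interactome, file.path(od, "interactome"))
    for (nm in names(subnets)) {
      write_network(subnets[[nm]], file.path(od, paste0("subnetwork_", nm)))
      write_table(data.frame(replicate = seq_len(nulls[[nm]]$reps),
                             nodes = nulls[[nm]]$replicate_node_counts,
                             edges = nulls[[nm]]$replicate_edge_counts),
                  file.path(od, paste0("null_", nm, ".tsv")))
      write_table(bip_rows[[nm]], file.path(od, paste0("pathway_enrichment_", nm, ".tsv")))
      write_table(bip_subnets[[nm]]$edges, file.path(od, paste0("bipartite_", nm, ".tsv")))
    }
    write_table(panel, file.path(od, "enrichment_panel.tsv"))
    write_table(overlaps, file.path(od, "pathway_overlap.tsv"))
    if (!is.null(converged_ppi)) {
      write_network(converged_ppi$module, file.path(od, "converged_module"))
      write_table(converged_ppi$overlap, file.path(od, "converged_overlap.tsv"))
      write_table(converged_pathways$module$edges,
                  file.path(od, "converged_pathway_module.tsv"))
      write_table(converged_pathways$gene_hubs,
                  file.path(od, "converged_pathway_hubs.tsv"))
    }
    null_summary <- lapply(nulls, function(nd) {
      list(observed_nodes = nd$observed_nodes, observed_edges = nd$observed_edges,
           p_nodes = nd$p_nodes, p_edges = nd$p_edges, reps = nd$reps)
    })
    jsonlite::write_json(list(
      interactome = network_summary(interactome),
      subnetworks = lapply(subnets, network_summary),
      nulls = null_summary
    ), file.path(od, "summary.json"), auto_unbox = TRUE, digits = NA)
    TRUE
  })

  artifacts <- list.files(config$out_dir, full.names = TRUE)
  artifacts <- artifacts[!basename(artifacts) %in% "manifest.json"]
  manifest <- list(
    rng_seed = config$rng_seed,
    created = format(t0, "%Y-%m-%dT%H:%M:%S"),
    elapsed_s = as.numeric(Sys.time() - t0, "secs"),
    stages = stages,
    config = {
      cfg <- config[setdiff(names(config), "paths")]
      cfg$sim <- as.list(unclass(cfg$sim))
      cfg
    },
    artifact_md5 = as.list(tools::md5sum(sort(artifacts)))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(
    config = config, inputs = inputs, expressed = expressed, coexpr = coexpr,
    interactome = interactome, subnetworks = subnets, nulls = nulls,
    enrichment = panel, bipartite = bip, pathway_rows = bip_rows,
    bipartite_subnetworks = bip_subnets, converged = converged_ppi,
    converged_pathways = converged_pathways, pathway_overlap = overlaps
  ))
}

# Reference worked-example counts: every printed enrichment fraction of the
# three seed sets across the nested universes of the motivating study, plus
# the four bipartite-vs-PPI pathway-overlap counts. Numerators/denominators
# are inputs; the fractions/percentages are recomputed at call time.
reference_counts <- function() {
  data.frame(
    id = c("t1", "t2", "t3", "t4", "t5", "t6", "t7", "t8", "t9",
           "t10", "t11", "t12", "t13"),
    label = c(
      "asd fraction in expressed genes", "asd fraction in DEGs",
      "asd fraction in DEG subnetwork",
      "ep fraction in expressed genes", "ep fraction in DEGs",
      "ep fraction in DEG subnetwork",
      "lm fraction in expressed genes", "lm fraction in DEGs",
      "lm fraction in DEG subnetwork",
      "deg bipartite/PPI pathway overlap %",
      "asd bipartite/PPI pathway overlap %",
      "ep bipartite/PPI pathway overlap %",
      "lm bipartite/PPI pathway overlap %"
    ),
    type = c(rep("fraction", 9), rep("percent", 4)),
    k = c(876L, 109L, 29L, 496L, 76L, 23L, 585L, 78L, 28L,
          86L, 82L, 24L, 132L),
    N = c(15254L, 1247L, 143L, 15254L, 1247L, 143L, 15254L, 1247L, 143L,
          123L, 121L, 48L, 183L),
    stringsAsFactors = FALSE
  )
}

#' Recompute the reference worked-example statistics
#'
#' Takes the printed numerator/denominator pairs of the reference analysis
#' (seed-set enrichment fractions over the expressed / DEG / DEG-subnetwork
#' universes, and bipartite-vs-PPI enriched-pathway overlap percentages) and
#' recomputes each statistic through the package's own operations —
#' [seed_fraction()] arithmetic for fractions, [pathway_list_overlap()] for
#' percentages.
#'
#' @return Data frame with `id`, `label`, `k`, `N`, `value` (fraction to 4
#'   decimals, or percentage to 1 decimal).
#' @export
worked_examples <- function() {
  ref <- reference_counts()
  value <- numeric(nrow(ref))
  for (i in seq_len(nrow(ref))) {
    k <- ref$k[i]; N <- ref$N[i]
    if (ref$type[i] == "fraction") {
      # synthetic symbol universe standing in for the unpublished gene lists:
      # only the counts matter for the fraction arithmetic
      u <- sprintf("u%06d", seq_len(N))
      value[i] <- seed_fraction(u[seq_len(k)], u)$fraction
    } else {
      a <- sprintf("pw%04d", seq_len(N))
      value[i] <- pathway_list_overlap(a, a[seq_len(k)])$percent
    }
  }
  data.frame(id = ref$id, label = ref$label, k = ref$k, N = ref$N,
             value = value, stringsAsFactors = FALSE)
}
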