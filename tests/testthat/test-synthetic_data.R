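small_cfg <- function(...) {
  sim_config(n_genes = 300, n_deg = 40, n_coexpr_blocks = 4, block_size = 15,
             seed_set_sizes = c(asd = 30, ep = 20), n_pathways = 12,
             planted_enriched_pathways = 2, planted_pathway_size = 20,
             planted_seed_members = 15, pathway_size_range = c(10, 40), ...)
}

test_that("sim_config validates its parameters", {
  expect_error(sim_config(n_genes = 5), "n_genes")
  expect_error(sim_config(ppi_mean_degree = 3000), "mean degree")
  expect_error(sim_config(within_block_correlation = 1.5), "correlation")
  expect_error(sim_config(seed_set_sizes = c(asd = 5000)), "exceeds")
  expect_error(sim_config(pathway_size_range = c(50, 10)), "pathway_size_range")
  expect_error(sim_config(n_deg = 1990, n_coexpr_blocks = 10, block_size = 20),
               "exceed")
})

ppi_cfg <- function(n_genes, ...) {
  sim_config(n_genes = n_genes, n_deg = 0, n_coexpr_blocks = 0, block_size = 0,
             seed_set_sizes = c(a = 2), n_pathways = 3,
             planted_enriched_pathways = 0, planted_pathway_size = 3,
             planted_seed_members = 2, pathway_size_range = c(3, 5), ...)
}

test_that("simulate_ppi matches the parameterization and is deterministic", {
  cfg <- ppi_cfg(100, ppi_model = "erdos_renyi", ppi_mean_degree = 4,
                 rng_seed = 1)
  el <- simulate_ppi(cfg)
  expect_equal(nrow(el), 200L)  # n*k/2
  expect_true(all(el$gene_a != el$gene_b))
  expect_identical(el, simulate_ppi(cfg))

  # preferential attachment with one edge per arrival gives a connected tree
  cfg2 <- ppi_cfg(10, ppi_model = "scale_free", ppi_mean_degree = 2,
                  rng_seed = 3)
  el2 <- simulate_ppi(cfg2)
  expect_equal(nrow(el2), 9L)
  g <- igraph::graph_from_data_frame(el2[, 1:2], directed = FALSE)
  expect_true(igraph::is_connected(g))
})

test_that("scale-free degree distribution is heavier-tailed than Erdos-Renyi", {
  sf <- simulate_ppi(ppi_cfg(1000, ppi_model = "scale_free",
                             ppi_mean_degree = 4, rng_seed = 5))
  er <- simulate_ppi(ppi_cfg(1000, ppi_model = "erdos_renyi",
                             ppi_mean_degree = 4, rng_seed = 5))
  max_deg <- function(el) {
    max(table(c(el$gene_a, el$gene_b)))
  }
  expect_gt(max_deg(sf), max_deg(er))
})

test_that("simulate_expression is deterministic and plants the configured DEGs", {
  cfg <- small_cfg(rng_seed = 11)
  m1 <- simulate_expression(cfg)
  m2 <- simulate_expression(cfg)
  expect_identical(m1$counts, m2$counts)
  expect_identical(m1$fpkm, m2$fpkm)

  deg <- attr(m1, "planted_deg")
  expect_equal(length(deg), 40L)
  expect_equal(sum(deg$regulation == "up"), round(40 * 787 / 1247))
  expect_identical(deg$genes, planted_deg_set(cfg)$genes)

  # planted upregulated genes have a visibly higher ko-group mean
  ko <- m1$samples$group == "ko"
  up <- deg$genes[deg$regulation == "up"]
  ratio <- rowMeans(m1$counts[up, ko]) / pmax(rowMeans(m1$counts[up, !ko]), 1)
  expect_gt(median(ratio), 1.5)
})

test_that("null configuration (n_deg = 0) leaves group means balanced", {
  cfg <- sim_config(n_genes = 400, n_deg = 0, n_coexpr_blocks = 0,
                    block_size = 0, rng_seed = 17)
  m <- simulate_expression(cfg)
  ko <- m$samples$group == "ko"
  lr <- log2((rowMeans(m$counts[, ko]) + 1) / (rowMeans(m$counts[, !ko]) + 1))
  expect_lt(abs(mean(lr)), 0.1)
})

test_that("within-block correlation of 1 gives near-perfect FPKM correlation", {
  cfg <- sim_config(n_genes = 30, n_deg = 0, n_coexpr_blocks = 1,
                    block_size = 10, within_block_correlation = 1,
                    seed_set_sizes = c(a = 5), n_pathways = 3,
                    planted_enriched_pathways = 0, planted_pathway_size = 5,
                    planted_seed_members = 3, pathway_size_range = c(5, 10),
                    rng_seed = 23)
  m <- simulate_expression(cfg)
  block <- attr(m, "block")
  genes <- names(block)[block == 1]
  cm <- cor(t(m$fpkm[genes, ]))
  expect_true(all(cm[upper.tri(cm)] > 0.99))
})

test_that("block correlation recovers the generative rho within 0.1 (Monte Carlo)", {
  rs <- vapply(1:500, function(i) {
    cfg <- sim_config(n_genes = 25, n_deg = 0, n_coexpr_blocks = 1,
                      block_size = 20, within_block_correlation = 0.9,
                      seed_set_sizes = c(a = 5), n_pathways = 3,
                      planted_enriched_pathways = 0, planted_pathway_size = 5,
                      planted_seed_members = 3, pathway_size_range = c(5, 10),
                      rng_seed = 10000 + i)
    m <- simulate_expression(cfg)
    block <- attr(m, "block")
    cm <- cor(t(m$fpkm[names(block)[block == 1], ]))
    mean(cm[upper.tri(cm)])
  }, 0.0)
  expect_lt(abs(mean(rs) - 0.9), 0.1)
})

test_that("seed sets respect size, planting and determinism", {
  cfg <- small_cfg(rng_seed = 31)
  deg <- planted_deg_set(cfg)
  ss <- simulate_seed_sets(cfg, deg)
  expect_named(ss, c("asd", "ep"))
  expect_equal(length(ss$asd), 30L)
  expect_identical(ss$asd$genes, simulate_seed_sets(cfg, deg)$asd$genes)

  # odds = Inf draws entirely from the DEGs
  cfg_inf <- small_cfg(planted_enrichment_odds = Inf, rng_seed = 31)
  ss_inf <- simulate_seed_sets(cfg_inf, deg)
  expect_true(all(ss_inf$asd$genes %in% deg$genes))
})

test_that("odds = 1 gives no enrichment; odds = 3 is recovered (Monte Carlo)", {
  n_deg <- 40L; n_genes <- 300L; sz <- 30L
  overlap <- function(odds, seeds) {
    vapply(seeds, function(s) {
      cfg <- small_cfg(planted_enrichment_odds = odds, rng_seed = s)
      deg <- planted_deg_set(cfg)
      length(intersect(simulate_seed_sets(cfg, deg)$asd$genes, deg$genes))
    }, 0L)
  }
  # exact mean of the noncentral hypergeometric draw count, computed from the
  # density directly (independent of the sampling code path)
  nchg_mean <- function(psi) {
    k <- 0:min(sz, n_deg)
    w <- choose(n_deg, k) * choose(n_genes - n_deg, sz - k) * psi^k
    sum(k * w) / sum(w)
  }
  ov1 <- overlap(1, 1:400)
  expect_lt(abs(mean(ov1) - nchg_mean(1)), 4 * sd(ov1) / sqrt(length(ov1)))
  # odds = 1 means the DEG fraction in the seed set matches the universe rate
  expect_lt(abs(mean(ov1) / sz - n_deg / n_genes), 0.02)

  ov3 <- overlap(3, 1:1000)
  expect_lt(abs(mean(ov3) - nchg_mean(3)), 4 * sd(ov3) / sqrt(length(ov3)))
  # moment-matched odds estimate brackets the planted value
  psi_hat <- uniroot(function(p) nchg_mean(p) - mean(ov3), c(1, 10))$root
  expect_gt(psi_hat, 2.5)
  expect_lt(psi_hat, 3.5)
})

test_that("planted pathways are enriched below 1e-6 by construction; GMT is deterministic", {
  cfg <- small_cfg(rng_seed = 41)
  deg <- planted_deg_set(cfg)
  ss <- simulate_seed_sets(cfg, deg)
  gmt <- simulate_pathways(cfg, ss)
  expect_length(gmt, 12L)

  planted <- gmt[grepl("^PLANTED", vapply(gmt, `[[`, "", "pathway_id"))]
  expect_length(planted, 2L)
  for (rec in planted) {
    target <- sub("^PLANTED\\d+_", "", rec$pathway_id)
    x <- length(intersect(rec$members, ss[[target]]$genes))
    expect_gte(x, 10L)
    p <- oracle_hyper_tail(x, m = length(rec$members), N = cfg$n_genes,
                           n = length(ss[[target]]$genes))
    expect_lt(p, 1e-6)
  }

  p1 <- tempfile(); p2 <- tempfile()
  write_gmt(gmt, p1)
  write_gmt(simulate_pathways(cfg, ss), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("simulate_all writes a complete readable input bundle", {
  dir <- tempfile()
  sim <- simulate_all(small_cfg(rng_seed = 51), dir = dir)
  expect_setequal(
    list.files(dir),
    c("ppi.tsv", "counts.tsv", "fpkm.tsv", "gene_lengths.tsv", "deg.tsv",
      "asd.txt", "ep.txt", "pathways.gmt")
  )
  deg_back <- read_gene_list(file.path(dir, "deg.tsv"))
  expect_setequal(deg_back$genes, sim$deg$genes)
  expect_equal(deg_back$regulation[deg_back$genes],
               sim$deg$regulation[deg_back$genes])
  ppi_back <- read_edge_list(file.path(dir, "ppi.tsv"))
  expect_equal(nrow(ppi_back), nrow(sim$ppi))
})
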