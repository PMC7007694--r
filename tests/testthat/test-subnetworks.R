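test_that("extraction follows the dual-support recruitment rule (hand trace)", {
  # A-B(both), A-C(both), C-D(ppi only), D-E(both); seeds {A, E}:
  # B, C recruited via dual edges to A; D recruited via dual edge to E;
  # C-D appears as an induced PPI-only edge
  net <- toy_interactome(data.frame(
    from = c("A", "A", "C", "D"), to = c("B", "C", "D", "E"),
    support = c("both", "both", "ppi", "both")
  ))
  sub <- extract_seed_subnetwork(net, gene_set(c("A", "E"), name = "toy"))
  expect_setequal(igraph::V(sub)$name, c("A", "B", "C", "D", "E"))
  el <- apply(igraph::as_edgelist(sub), 1,
              function(r) paste(sort(r), collapse = "-"))
  expect_setequal(el, c("A-B", "A-C", "C-D", "D-E"))
  roles <- setNames(igraph::V(sub)$role, igraph::V(sub)$name)
  expect_equal(roles[["A"]], "seed")
  expect_equal(roles[["E"]], "seed")
  expect_equal(roles[["B"]], "neighbor")
})

test_that("seeds with only ppi-only incident edges produce an empty subnetwork", {
  net <- toy_interactome(data.frame(
    from = c("A", "B"), to = c("X", "Y"), support = c("ppi", "ppi")
  ))
  sub <- extract_seed_subnetwork(net, c("A", "B"))
  expect_equal(igraph::vcount(sub), 0L)
})

test_that("regulation labels travel onto subnetwork nodes", {
  net <- toy_interactome(data.frame(
    from = "A", to = "B", support = "both"
  ))
  seeds <- gene_set(c("A"), regulation = c(A = "up"), name = "deg")
  sub <- extract_seed_subnetwork(net, seeds)
  reg <- setNames(igraph::V(sub)$regulation, igraph::V(sub)$name)
  expect_equal(reg[["A"]], "up")
  expect_equal(reg[["B"]], "none")
})

test_that("absent seeds warn and give an empty subnetwork", {
  net <- toy_interactome(data.frame(from = "A", to = "B", support = "both"))
  expect_warning(sub <- extract_seed_subnetwork(net, c("Z")), "no seed")
  expect_equal(igraph::vcount(sub), 0L)
})

test_that("extraction is monotone in the seed set", {
  net <- random_interactome(40, 90, dual_frac = 0.5, seed = 21)
  nodes <- igraph::V(net)$name
  for (trial in 1:10) {
    set.seed(trial)
    small <- sample(nodes, 5)
    big <- union(small, sample(nodes, 5))
    sub_small <- suppressWarnings(extract_seed_subnetwork(net, small))
    sub_big <- suppressWarnings(extract_seed_subnetwork(net, big))
    expect_true(all((igraph::V(sub_small)$name %||% character()) %in%
                      (igraph::V(sub_big)$name %||% character())))
  }
})

test_that("shuffle_null with seeds = all nodes is permutation invariant (p = 1)", {
  net <- random_interactome(30, 70, dual_frac = 0.5, seed = 31)
  # all-seed extraction is invariant under relabeling, so the null degenerates
  expect_warning(
    nd <- shuffle_null(net, igraph::V(net)$name, reps = 20, rng_seed = 1),
    "degenerate")
  expect_true(all(nd$replicate_node_counts == nd$observed_nodes))
  expect_true(all(nd$replicate_edge_counts == nd$observed_edges))
  expect_equal(nd$p_nodes, 1)
  expect_equal(nd$p_edges, 1)
})

test_that("a vertex-transitive interactome gives a degenerate null that is flagged", {
  ring <- igraph::make_ring(8)
  igraph::V(ring)$name <- paste0("r", 1:8)
  igraph::E(ring)$ppi <- TRUE
  igraph::E(ring)$coexpr <- TRUE
  class(ring) <- c("tissue_interactome", class(ring))
  expect_warning(nd <- shuffle_null(ring, "r1", reps = 25, rng_seed = 2),
                 "degenerate")
  expect_true(nd$degenerate)
  expect_equal(length(unique(nd$replicate_node_counts)), 1L)
})

test_that("shuffle_null is reproducible under a fixed master seed", {
  net <- random_interactome(50, 120, dual_frac = 0.5, seed = 41)
  seeds <- igraph::V(net)$name[1:8]
  n1 <- shuffle_null(net, seeds, reps = 30, rng_seed = 99)
  n2 <- shuffle_null(net, seeds, reps = 30, rng_seed = 99)
  expect_identical(n1$replicate_node_counts, n2$replicate_node_counts)
  expect_identical(n1$replicate_edge_counts, n2$replicate_edge_counts)
})

test_that("betweenness closed forms: path and star", {
  path <- igraph::make_graph(~ a - b, b - c)
  rk <- betweenness_ranking(path, k = 3)
  expect_equal(rk$gene[1], "b")
  expect_equal(rk$betweenness, c(1, 0, 0))

  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("h", paste0("l", 1:4))
  rk2 <- betweenness_ranking(star, k = 1)
  expect_equal(rk2$gene, "h")
  expect_equal(rk2$betweenness, 6)  # C(4,2) dependent pairs
})

test_that("betweenness matches exhaustive path enumeration on small random graphs", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(5:8, 1)
    g <- igraph::sample_gnp(n, 0.45)
    igraph::V(g)$name <- letters[1:n]
    rk <- suppressWarnings(betweenness_ranking(g, k = n))
    want <- oracle_betweenness(g)
    expect_equal(setNames(rk$betweenness, rk$gene)[names(want)], want,
                 tolerance = 1e-12)
  }
})

test_that("betweenness ties break by degree then symbol, and big k warns", {
  # two components: a triangle (all betweenness 0) plus an isolated pair
  g <- igraph::make_graph(~ a - b, b - c, a - c, x - y)
  expect_warning(rk <- betweenness_ranking(g, k = 10), "exceeds")
  expect_equal(nrow(rk), 5L)
  expect_true(all(rk$betweenness == 0))
  # degree 2 nodes (triangle) first, then lexicographic
  expect_equal(rk$gene, c("a", "b", "c", "x", "y"))
})

test_that("converged_module intersects node sets and induces interactome edges", {
  net <- random_interactome(30, 80, dual_frac = 0.8, seed = 51)
  nodes <- igraph::V(net)$name
  s1 <- suppressWarnings(extract_seed_subnetwork(net, nodes[1:12]))
  s2 <- suppressWarnings(extract_seed_subnetwork(net, nodes[5:16]))
  mod <- converged_module(list(s1, s2), net)
  want <- intersect(igraph::V(s1)$name, igraph::V(s2)$name)
  expect_setequal(mod$shared_nodes, want)
  expect_equal(mod$overlap$n_nodes[nrow(mod$overlap)], length(want))
  expect_setequal(igraph::V(mod$module)$name, want)

  # identical subnetworks: module nodes = that subnetwork's nodes
  mod_same <- converged_module(list(s1, s1), net)
  expect_setequal(mod_same$shared_nodes, igraph::V(s1)$name)

  # disjoint subnetworks: empty module, not an error
  g1 <- toy_interactome(data.frame(from = "A", to = "B", support = "both"))
  sub_a <- extract_seed_subnetwork(g1, c("A", "B"))
  g2 <- toy_interactome(data.frame(from = "X", to = "Y", support = "both"))
  sub_x <- extract_seed_subnetwork(g2, c("X", "Y"))
  mod_empty <- converged_module(list(sub_a, sub_x), net)
  expect_length(mod_empty$shared_nodes, 0L)
})

test_that("seeds planted in dense co-expression blocks beat the null (power)", {
  # ten 6-gene blocks at rho = 0.95; PPI carries a clique inside each block
  # plus a sparse background; seeding one gene per block recruits the rest of
  # every block through dual-support edges, which random label placements
  # rarely reproduce
  cfg <- sim_config(n_genes = 200, n_deg = 0, n_coexpr_blocks = 10,
                    block_size = 6, within_block_correlation = 0.95,
                    seed_set_sizes = c(a = 5), n_pathways = 3,
                    planted_enriched_pathways = 0, planted_pathway_size = 5,
                    planted_seed_members = 3, pathway_size_range = c(5, 10),
                    rng_seed = 61)
  m <- simulate_expression(cfg)
  block <- attr(m, "block")
  bg <- simulate_ppi(cfg)
  cliques <- do.call(rbind, lapply(1:10, function(b) {
    t(combn(names(block)[block == b], 2))
  }))
  ppi <- rbind(bg[, 1:2],
               data.frame(gene_a = cliques[, 1], gene_b = cliques[, 2]))
  net <- build_tissue_interactome(ppi, rownames(m$counts))
  net <- annotate_coexpression(net, suppressMessages(coexpression_edges(m)))
  seeds <- vapply(1:10, function(b) names(block)[block == b][1], "")
  nd <- shuffle_null(net, seeds, reps = 200, rng_seed = 71)
  expect_gt(nd$observed_nodes,
            quantile(nd$replicate_node_counts, 0.95))
})
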