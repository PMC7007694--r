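# Independent oracles and toy-fixture builders. Everything here is written
# against first principles (enumeration, closed forms), never by calling the
# code paths under test.

# Exact two-tailed Fisher p by enumerating all margin-fixed 2x2 tables and
# summing integer table counts (exact in double precision for totals <= 40).
oracle_fisher_p <- function(a, b, c, d) {
  N <- a + b + c + d
  K <- a + b
  n <- a + c
  lo <- max(0, n - (N - K))
  hi <- min(n, K)
  x <- lo:hi
  counts <- choose(K, x) * choose(N - K, n - x)
  obs <- counts[x == a]
  sum(counts[counts <= obs]) / choose(N, n)
}

# One-sided hypergeometric over-representation tail P(X >= x) by direct
# tail summation of binomial-coefficient ratios.
oracle_hyper_tail <- function(x, m, N, n) {
  hi <- min(m, n)
  if (x > hi) return(0)
  j <- max(x, max(0, n - (N - m))):hi
  sum(choose(m, j) * choose(N - m, n - j)) / choose(N, n)
}

# Unnormalized betweenness by exhaustive enumeration of simple paths: for
# every unordered pair, enumerate all simple paths by DFS, keep the shortest,
# and credit each interior vertex with its fraction of shortest paths.
oracle_betweenness <- function(g) {
  n <- igraph::vcount(g)
  adj <- lapply(seq_len(n), function(v) as.integer(igraph::neighbors(g, v)))
  btw <- numeric(n)
  enum_paths <- function(cur, target, visited) {
    if (cur == target) return(list(visited))
    out <- list()
    for (w in adj[[cur]]) {
      if (!w %in% visited) {
        out <- c(out, enum_paths(w, target, c(visited, w)))
      }
    }
    out
  }
  if (n < 2) return(stats::setNames(btw, igraph::V(g)$name))
  for (s in 1:(n - 1)) {
    for (t in (s + 1):n) {
      paths <- enum_paths(s, t, s)
      if (!length(paths)) next
      lens <- lengths(paths)
      shortest <- paths[lens == min(lens)]
      sigma <- length(shortest)
      for (p in shortest) {
        interior <- p[-c(1, length(p))]
        btw[interior] <- btw[interior] + 1 / sigma
      }
    }
  }
  stats::setNames(btw, igraph::V(g)$name)
}

# Annotated toy interactome from a data frame of (from, to, support) rows,
# support in {"ppi", "both"}.
toy_interactome <- function(edges) {
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE)
  igraph::E(g)$ppi <- TRUE
  igraph::E(g)$coexpr <- edges$support == "both"
  class(g) <- c("tissue_interactome", class(g))
  g
}

# Random annotated interactome for property tests: Erdos-Renyi topology with
# a fixed fraction of dual-support edges.
random_interactome <- function(n, m, dual_frac = 0.5, seed = 1) {
  set.seed(seed)
  g <- igraph::sample_gnm(n, m)
  igraph::V(g)$name <- sprintf("n%03d", seq_len(n))
  igraph::E(g)$ppi <- TRUE
  igraph::E(g)$coexpr <- runif(igraph::ecount(g)) < dual_frac
  class(g) <- c("tissue_interactome", class(g))
  g
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
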