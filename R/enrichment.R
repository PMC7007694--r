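#' Seed fraction within a gene universe
#'
#' @param seed_set A [gene_set()] or character vector of seed symbols.
#' @param universe A [gene_set()] or character vector (non-empty).
#' @return List with `k` (hits), `N` (universe size), `fraction` (`k/N`,
#'   rounded to 4 decimals).
#' @export
seed_fraction <- function(seed_set, universe) {
  u <- as_genes(universe, normalize = TRUE)
  if (!length(u)) stop_fmt("seed_fraction: empty universe")
  s <- as_genes(seed_set, normalize = TRUE)
  k <- length(intersect(s, u))
  N <- length(u)
  list(k = k, N = N, fraction = round(k / N, 4))
}

#' Bootstrap standard error of a seed fraction
#'
#' Resamples the universe membership-indicator vector with replacement `B`
#' times and returns the sample standard deviation of the resampled fractions.
#' As `B` grows this converges to the binomial closed form
#' `sqrt(p(1-p)/N)`.
#'
#' @param seed_set,universe As in [seed_fraction()].
#' @param B Number of bootstrap resamples (default 100).
#' @param rng_seed RNG seed.
#' @return Non-negative numeric scalar.
#' @export
bootstrap_se <- function(seed_set, universe, B = 100, rng_seed = 1) {
  u <- as_genes(universe, normalize = TRUE)
  if (!length(u)) stop_fmt("bootstrap_se: empty universe")
  ind <- u %in% as_genes(seed_set, normalize = TRUE)
  N <- length(u)
  fracs <- with_seed(rng_seed, {
    vapply(seq_len(B), function(b) mean(ind[sample.int(N, N, replace = TRUE)]),
           0.0)
  })
  stats::sd(fracs)
}

# Exact two-tailed p for a 2x2 table with fixed margins: sum the
# hypergeometric point probabilities of every table at least as extreme
# (point probability <= observed, with a small relative tolerance against
# floating-point ties).
fisher_p_from_table <- function(a, b, c_, d) {
  if (min(a, b, c_, d) < 0) stop_fmt("negative cell in 2x2 table")
  N <- a + b + c_ + d
  K <- a + b          # row-1 margin
  n <- a + c_         # column-1 margin
  lo <- max(0L, n - (N - K))
  hi <- min(n, K)
  x <- lo:hi
  probs <- stats::dhyper(x, K, N - K, n)
  obs <- probs[x == a]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

#' Exact two-tailed Fisher test for two seed fractions
#'
#' Compares `k1/N1` against `k2/N2`. When `nested = TRUE` the second universe
#' is a subset of the first (e.g. DEGs within all expressed genes) and the
#' 2x2 table is built on *disjoint* groups — the subset versus its complement:
#' `(k2, N2 - k2)` vs `(k1 - k2, (N1 - N2) - (k1 - k2))` — because putting
#' overlapping groups in one contingency table would double-count the subset.
#' The two-tailed p-value is the exact conventional one: the sum of
#' probabilities of all margin-fixed tables whose point probability does not
#' exceed that of the observed table.
#'
#' @param k1,N1 Hits and size of the first (larger, when nested) universe.
#' @param k2,N2 Hits and size of the second universe.
#' @param nested Is universe 2 a subset of universe 1? (default TRUE).
#' @return p-value in `(0, 1]`.
#' @export
fisher_two_tailed <- function(k1, N1, k2, N2, nested = TRUE) {
  stopifnot(k1 <= N1, k2 <= N2)
  if (nested) {
    a <- k2
    b <- N2 - k2
    c_ <- k1 - k2
    d <- (N1 - N2) - (k1 - k2)
    if (min(a, b, c_, d) < 0) {
      stop_fmt(paste0("inconsistent nested counts: universe 2 must be a ",
                      "subset of universe 1 (k1=%d N1=%d k2=%d N2=%d)"),
               k1, N1, k2, N2)
    }
  } else {
    a <- k1; b <- N1 - k1; c_ <- k2; d <- N2 - k2
  }
  fisher_p_from_table(a, b, c_, d)
}

#' Enrichment panel across seed sets and nested universes
#'
#' For every seed set and every universe: the seed fraction, its bootstrap
#' standard error, and the exact two-tailed Fisher p-value against the
#' previous (enclosing) universe. Universes must be supplied from largest to
#' smallest and be nested (e.g. expressed genes ⊃ DEGs ⊃ DEG-subnetwork
#' nodes), mirroring the three-bar enrichment panels of the analysis.
#'
#' Consecutive universes are usually nested (DEGs within expressed genes) and
#' then compared with the disjoint subset-vs-complement table; a universe that
#' is *not* a subset of its predecessor (e.g. subnetwork nodes, which include
#' non-seed neighbors) is compared as two separate groups instead.
#'
#' @param seed_sets Named list of [gene_set()]s (or character vectors).
#' @param universes Named list of universes, largest first.
#' @param B Bootstrap resamples for the standard error (default 100).
#' @param rng_seed Master RNG seed; each (seed set, universe) cell uses a
#'   derived stream.
#' @return Data frame of class `enrichment_panel` with one row per
#'   seed-set x universe: `seed_set`, `universe`, `k`, `N`, `fraction`, `se`,
#'   `fisher_p_vs_previous` (NA for the first universe).
#' @export
enrichment_panel <- function(seed_sets, universes, B = 100, rng_seed = 1) {
  if (is.null(names(seed_sets)) || is.null(names(universes))) {
    stop_fmt("seed_sets and universes must be named lists")
  }
  uni <- lapply(universes, as_genes)
  nested_in_prev <- c(FALSE, vapply(seq_along(uni)[-1], function(j) {
    all(uni[[j]] %in% uni[[j - 1]])
  }, TRUE))
  rows <- list()
  cell <- 0L
  for (s in names(seed_sets)) {
    prev <- NULL
    for (j in seq_along(uni)) {
      cell <- cell + 1L
      fr <- seed_fraction(seed_sets[[s]], uni[[j]])
      se <- bootstrap_se(seed_sets[[s]], uni[[j]], B = B,
                         rng_seed = rng_seed + cell)
      p <- NA_real_
      if (!is.null(prev)) {
        p <- fisher_two_tailed(prev$k, prev$N, fr$k, fr$N,
                               nested = nested_in_prev[j])
      }
      rows[[cell]] <- data.frame(
        seed_set = s, universe = names(uni)[j],
        k = fr$k, N = fr$N, fraction = fr$fraction, se = se,
        fisher_p_vs_previous = p, stringsAsFactors = FALSE
      )
      prev <- fr
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("enrichment_panel", class(out))
  out
}
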