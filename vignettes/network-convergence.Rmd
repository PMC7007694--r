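---
title: "Seed-gene subnetwork convergence analysis: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-gene subnetwork convergence analysis: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netconverge)
```

## The model

`netconverge` asks whether several seed-gene lists (differentially expressed
genes and disease/function candidate lists) converge on a shared region of a
tissue's molecular network. The analysis has three layers.

**Tissue interactome.** A physical PPI edge list is restricted to the genes
expressed in the tissue. Expression is defined by a hard count filter — raw
count strictly greater than 1 in at least 4 samples — chosen because it is
the filter used upstream of the differential-expression calls this pipeline
consumes. Cleanup is deterministic and ordered: duplicate records (in either
orientation) collapse to one undirected edge, self-loops are removed, then
zero-degree nodes are pruned. An explicit expressed-gene list can be supplied
instead of counts, because count-level criteria behind a published universe
are not always recoverable.

**Dual-support edges.** Pearson correlation of FPKM profiles is computed over
all samples, both groups pooled — the pipeline models one tissue-level
co-expression network, not per-genotype networks. An interactome edge with
|r| ≥ 0.75 gains the `coexpr` flag. Two unstated details are exposed as
flags with defaults:

* `mode = "absolute"` (|r| vs signed r ≥ cutoff): the unsigned convention is
  the default because a plain "correlation cutoff" most often means |r|, and
  anticorrelated partners are still co-regulated;
* `log_transform = FALSE`: correlation is computed on raw FPKM by default
  because no transform is stated in the motivating design; `log2(FPKM + 1)`
  is available for heavy-tailed data.

Co-expression is an edge *attribute*, never an edge source: a co-expressed
pair without physical interaction contributes nothing. This follows from the
visual grammar of the analysis this package reimplements, in which edges are
PPI-only or PPI+co-expression but never co-expression-only.

**Seed subnetworks.** For seed set $S$, the subnetwork contains
$(S \cap V) \cup \{v : \exists s \in S$ with a dual-support edge $s\!-\!v\}$,
with **all** interactome edges induced on that node set, then zero-degree
nodes pruned. The pivotal interpretation, recorded here because the
one-sentence extraction rule admits two readings: *recruitment* of a
neighbor requires dual support, but *induced* PPI-only edges among included
nodes are retained, and seed–seed edges need no dual support. Isolated seeds
are pruned by the zero-degree rule. Extraction is monotone in the seed set.

## The permutation null

"Shuffling the nodes" is implemented literally as a uniform random
permutation of node labels on the fixed topology; support flags stay with the
topology's edges, and the same seed list is re-extracted. This tests whether
the seeds occupy an unusually dual-support-rich neighborhood, while
preserving the graph and its flag structure exactly. A degree-preserving
edge-rewiring null would test a different hypothesis (topology randomness)
and is deliberately not provided.

* Empirical p uses the add-one (phantom-replicate) estimator
  $p = (1 + \#\{r \ge \mathrm{obs}\})/(R+1)$, standard permutation-test
  practice that avoids $p = 0$.
* Replicate $i$ draws from the RNG stream `rng_seed + i`, so results are
  independent of execution order and reproducible in parallel settings.
* A degenerate null (all replicates identical, e.g. on vertex-transitive
  graphs or all-node seed lists) is detected and flagged.
* Calibration: for uniformly random seed sets, the empirical p is itself
  approximately Uniform(0,1); the acceptance suite checks this with a
  Kolmogorov–Smirnov test over 200 draws at 99 replicates.

## Enrichment statistics

The seed fraction $k/N$ is reported with a bootstrap standard error: the
universe membership-indicator vector is resampled with replacement $B = 100$
times (the reference design's resample count) and the SE is the standard
deviation of the resampled fractions; as $B \to \infty$ this converges to
$\sqrt{p(1-p)/N}$, which the tests verify at $B = 10^4$.

Fractions across universes are compared with an exact two-tailed Fisher test
(sum of all margin-fixed tables with point probability ≤ the observed
table's). When universe 2 is nested in universe 1 — DEGs inside expressed
genes — the 2×2 table is built on *disjoint* groups, subset vs complement:
$(k_2,\,N_2-k_2)$ vs $(k_1-k_2,\,(N_1-N_2)-(k_1-k_2))$. Putting overlapping
groups into one contingency table double-counts the subset; because the
reference analysis does not state its construction, its printed p-values are
not acceptance targets here, only the fractions are. The third universe of
the standard panel (DEG-subnetwork nodes) contains non-DEG neighbors and is
therefore *not* nested in the DEG universe; the panel detects this and falls
back to an ordinary two-group table for that comparison.

## Pathway layer

The gene–pathway bipartite network is strictly two-mode, built from GMT
annotations restricted to the expressed universe. A pathway is kept for a
seed set when the one-sided hypergeometric over-representation tail satisfies
p < 10⁻⁶ **and** the pathway contains ≥ 10 seed genes — strict inequalities
exactly as stated, with "contains at least ten seed genes" read as seed
*hits* ($x \ge 10$), not pathway size. One-sided (not two-tailed) is used
because "enriched for" is directional. Two open choices and their defaults:

* the hypergeometric population defaults to the genes present in the
  bipartite network (genes with ≥ 1 annotation), with `universe_genes` to use
  the full expressed universe instead — annotation coverage differs between
  the two and the reference analysis does not say which it used;
* the PPI-side pathway lists for the bipartite-vs-PPI concordance comparison
  are produced by running the same hypergeometric keep rule on PPI-subnetwork
  node sets, standing in for an external annotation service. The comparison
  operation (counts and one-decimal percentages) is the deliverable.

Converged modules intersect node sets (PPI side) or kept-pathway and
gene-node sets (bipartite side), with edges induced from the common parent
network; hub genes are ranked by shared-pathway degree.

## Betweenness ranking

Hubs are ranked by unnormalized, unweighted shortest-path betweenness
(rankings are invariant to normalization). Ties break by descending degree,
then lexicographic symbol, so rankings are fully deterministic. The tests pin
the implementation to an exhaustive shortest-path enumeration oracle on all
fixture graphs up to 8 nodes.

## The synthetic world

The generator's defaults are a ~7.6× scale-down of the reference design,
fixed once:

| parameter | default | rationale |
|---|---|---|
| genes | 2000 | 15,254 expressed genes scaled to desk scale |
| samples | 3 + 3 | the reference design (three RNA pools per genotype) |
| planted DEGs | 160 (63% up) | 1247 DEGs, 787 up / 460 down, same ratio |
| seed sets | asd 115, ep 65, lm 77 | 876/496/585 scaled |
| PPI mean degree | 4.4 | 2 × 9205 edges / 4202 nodes |
| block correlation | 0.9, 10 blocks × 20 | strong co-expression structure at n = 6 |
| DEG \|log2 FC\| | 1.5 | comfortably detectable at n = 3 per group |
| NB dispersion | 0.1 | typical bulk RNA-seq |
| enrichment odds | 3 | planted DEG–seed association |
| planted pathways | 3 × (30 genes, 25 seed members) | targets p ≪ 10⁻⁶ with ≥ 10 hits |

Counts are negative-binomial through a Gaussian copula: block genes share a
per-sample latent factor with loading $\sqrt{\rho}$, and counts are the NB
quantile transform of the latent score. This is the simplest construction
giving count-valued data *and* a tunable Pearson correlation near the 0.75
cutoff; the monotone NB transform attenuates the latent correlation slightly
(the tests require recovery of ρ = 0.9 within ±0.1 at n = 6, which is also
the honest noise level of correlation estimates from six samples). Seed sets
draw their DEG-overlap count from Fisher's noncentral hypergeometric
distribution with odds ψ, so the planted odds ratio is exactly the
conditional odds ratio being estimated downstream. FPKM uses fixed synthetic
gene lengths (uniform 500–5000 bp) and a constant nominal library size: at
2000 genes, realized column sums are dominated by the simulated genes
themselves, and normalizing by them would cancel shared block variation — a
compositional artifact that real ~15k-gene libraries do not show.

What the generator does **not** emulate: read-level noise and mapping
artifacts (counts are drawn directly), annotation bias (pathways sample genes
uniformly), correlated seed lists (candidate sets are independent given the
DEG overlap), and the heavy literature-driven degree bias of curated PPI
databases (preferential attachment gives a heavy tail but not curation
structure). A green test therefore establishes that the *operations* are
correct and the planted-signal recovery is calibrated — not that any
particular biological claim reproduces.

## Numerical and degenerate-input choices

* Exact tests sum `dhyper` point masses with a $1 + 10^{-7}$ relative
  tolerance against floating-point ties (the convention of base R's exact
  test); the test suite checks exact agreement with integer enumeration on
  every 2×2 table with total ≤ 40.
* Constant-profile genes have undefined correlation: they contribute no
  co-expression edges and are counted in a message.
* Empty intersections (expressed ∩ PPI, converged modules, bipartite
  restrictions) yield empty objects with warnings, not errors; inconsistent
  nested Fisher counts are errors.
* Gene symbols are case-normalized (first letter upper) at parse time only;
  internal joins are exact-match. The fraction statistics additionally
  normalize both sides, making them invariant to input case.
* All randomness flows through per-call seeds derived from one master seed;
  identical configurations give byte-identical outputs.

## Known limitations

* The reference analysis's headline numbers (4204-node interactome, 143-node
  DEG subnetwork, 17-node converged module, 37 shared pathways) are
  data-dependent and cannot be reproduced without its unpublished expression
  matrix and database snapshots; the package reproduces the *procedure* and
  its printed worked-example statistics.
* Node-label permutation is the only null; no degree-preserving rewiring.
* Symbol-only identifiers: no orthology or identifier mapping.
* The bipartite layer ignores pathway topology (memberships only).
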