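---
title: "Identifying characteristic genes with network centrality and dense-module mining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying characteristic genes with network centrality and dense-module mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncmnet)
```

## The problem

Tumor-vs-normal expression studies routinely produce lists of
differentially expressed genes (DEGs), but a flat list says nothing about
which of those genes sit at functionally important positions. A standard
remedy is to place the DEGs in a protein-protein interaction network and
rank them by topology: well-connected, centrally located genes are better
candidates for characteristic (marker) genes than peripheral ones. ncmnet
implements that pipeline end to end -- DEG screening, network
construction, centrality ranking with a composite score, high-density
subgraph mining, and gene-set enrichment -- together with seeded
synthetic generators so the whole chain can be validated against known
ground truth.

## DEG screening

Each dataset is a log2-scale matrix of genes by samples with a
case/control label per sample. Per gene we compute the log2 fold change
(difference of group means) and an ordinary pooled-variance two-sample
t-test; Welch's unequal-variance form is available via `welch = TRUE`
for data with strong per-group variance differences. P-values are
Benjamini-Hochberg adjusted across the genes of the dataset, and a gene
is called *up* when `p_adj < alpha` and `logFC > lfc_cut`, *down* when
`p_adj < alpha` and `logFC < -lfc_cut`, with strict inequalities; the
defaults are `alpha = 0.05` and `lfc_cut = 2` (a 4-fold change). These
cutoffs are deliberately conservative: with 10 samples per group and
unit-variance log2 noise they give near-perfect precision at high
sensitivity for 3-log2-unit shifts (the acceptance script measures
both).

Genes with any missing or non-finite value are dropped at dataset
construction and recorded, not imputed -- imputation would silently
couple the test statistics across genes. Duplicate gene symbols are
rejected rather than averaged, since collapsing policies (mean, max,
first probe) change results in ways the user should choose explicitly
upstream.

Calls from several datasets are merged by `integrate_degs()`: the union
of up/down calls, de-duplicated by symbol, with per-gene provenance. A
gene called up in one dataset and down in another is kept and flagged
`"conflict"` rather than dropped, because dropping would silently shrink
the network node set; downstream analyses can filter on the flag.

## Network construction

Interactions are read from STRING-style flat files (`gene gene
combined_score`); scores on the 0--1000 integer scale are divided by
1000, so edge weights always live in (0, 1]. Symbol matching is exact
after upper-casing -- identifier aliasing must be resolved upstream,
which is a documented limitation. The graph is simple and undirected:
self-loops are dropped, duplicate unordered pairs keep the **maximum**
score (a deterministic, order-independent choice), and nodes without any
surviving edge are absent from the result. Restricting to the integrated
DEG set happens at construction, before isolated-node removal, so a DEG
with no interactions inside the set never appears as a stray singleton.

## Centralities and the NCM

For a node $v$ in a component of $n$ nodes:

* degree centrality $DC(v) = \deg(v)/(n-1)$;
* betweenness $BC(v) = \sum_{i \ne j \ne v} \sigma_{ivj}/\sigma_{ij}$,
  unnormalized, summed over unordered same-component pairs;
* closeness is kept in its **farness** form
  $CC(v) = \frac{1}{n-1}\sum_j d_{vj}$ -- smaller is more central;
* clustering coefficient $CLC(v) = 2e/(k(k-1))$ over the $k$ neighbors
  of $v$ and the $e$ edges among them, defined as 0 when $k < 2$;
* eccentricity centrality $EC(v) = 1/\max_u d_{vu}$, the reciprocal of
  the eccentricity.

The composite Normalized Centrality Measure is

$$NCM(v) = \left(\frac{BC(v)}{BC_{max}} + \frac{DC(v)}{DC_{max}}\right)
\Big/ \frac{CC(v)}{CC_{max}},$$

with the maxima taken over the whole network. It rewards nodes that are
simultaneously local hubs (degree), global brokers (betweenness) and
close to everything (small farness, which appears in the denominator so
central nodes score high). When $BC_{max} = 0$ -- complete graphs have
no intermediate vertices -- the betweenness term is taken as 0, so every
node of $K_n$ scores exactly 1. On the 5-star the center scores
$(6/6 + 1/1)/(1/1.75) = 3.5$ and each leaf $0.25$; the NCM ranks the
star center strictly first for every star size.

Numerical choices worth stating:

* **Unweighted paths by default.** Edge weights are confidence scores,
  not distances, and the five measures read naturally as topological.
  `weighted = TRUE` uses length $1 -$ score so that high-confidence
  edges are short; a score of exactly 1 would give a zero-length edge,
  which breaks shortest-path counting, so such edges get a tiny positive
  length (1e-6). Both modes are checked against the same enumeration
  oracle in the tests.
* **Disconnected networks.** $n$ and all distances are per component
  (avoiding infinite farness), while the NCM maxima span the whole
  network so one global ranking results.
* **Sort directions.** DC, BC, CLC and NCM rank descending and CC
  ascending. EC is stored as a reciprocal, so large values mean small
  eccentricity; the default ranking is therefore descending, but the
  opposite convention also circulates (reading raw eccentricity,
  ascending), so `rank_nodes(..., ec_direction = "asc")` exposes it
  rather than silently resolving the ambiguity. Ties are always broken
  by gene symbol, making every ranking deterministic.

## Dense-module mining

Maximal cliques are enumerated with pivoted Bron-Kerbosch (via igraph)
and verified against brute-force subset checking in the tests. A node's
Maximal Clique Centrality is

$$MCC(v) = \sum_{C \in S(v)} (|C|-1)!$$

over the maximal cliques containing $v$. The factorial form is used
exactly as written; the variant that substitutes the plain degree for
nodes with no inter-neighbor edges is **not** applied. The
top-`n_hubs` MCC nodes seed module growth. The hub count (default 10)
and the density threshold `theta` (default 0.6) are exposed parameters:
neither has a canonical value, and sensible defaults are a hub list
comparable to a top-k gene table and a threshold halfway between a
sparse background and a clique.

Each hub's largest maximal clique (ties: lexicographically smallest
set) is the seed; the module then grows greedily by the neighbor that
maximizes the density ("cliqueness") of the enlarged set,

$$\mathrm{cliqueness}(G) = \frac{E(G)}{\binom{|V(G)|}{2}},$$

subject to two acceptance conditions: the enlarged set must keep
cliqueness $\ge \theta$, **and** the incoming node must be adjacent to
at least $\theta \cdot m$ of the current $m$ members (the quasi-clique
connectivity condition). The density condition alone is too weak at the
boundary: a module of $m$ nodes that is itself a clique tolerates a
single-edge hanger-on whenever $\binom{m}{2} + 1 \ge \theta
\binom{m+1}{2}$ (for $m = 8$, $\theta = 0.8$: $29/36 \approx 0.81$), so
dense cores would slowly accrete loosely attached background nodes. The
connectivity condition removes exactly that failure mode while leaving
genuinely dense growth untouched, and it preserves a useful invariant:
because the greedy pick maximizes the enlarged density -- a quantity
monotone in the candidate's edge count into the module, which is also
what the connectivity condition tests -- raising `theta` can only
truncate a growth trajectory, never redirect it, so modules shrink or
stay equal as `theta` rises. At `theta = 1` every returned module is a
clique.

Grown modules below `min_size` (default 3) are discarded; modules with
Jaccard similarity at least 0.8 are considered duplicates and the larger
is kept. Overlap below that threshold is deliberately allowed -- one
gene can legitimately anchor several modules.

## Enrichment

Gene-set enrichment is an offline hypergeometric over-representation
test against user-supplied GMT collections: for a universe of $N$ genes,
a set of $K$, a testable query of $n$ and an overlap of $k$, the
one-sided upper tail $P(X \ge k)$, BH-adjusted across the collection.
The universe defaults to the union of all set members and should be
overridden with an explicit background (for instance the network node
set) when one exists; web services' proprietary backgrounds and modified
statistics are not imitated. Only over-representation is tested --
depletion is not a use case here.

## The synthetic generators, and what passing means

`simulate_expression()` draws per-gene baselines from Normal(8, 1) (the
intensity spread of a typical log2 microarray), adds Gaussian noise per
sample, and shifts the case-group mean of the first `n_de` genes by
`true_lfc`. `simulate_network()` wires an Erdos-Renyi background at
`p_background` and plants disjoint dense blocks at their own densities,
all with weight 1. Both require an explicit seed and restore the
caller's RNG state, so identical specs give byte-identical outputs.

These generators are intentionally idealized: no probe effects, batch
structure, correlated genes, heavy-tailed noise, or scale-free degree
distributions. Passing the recovery tests therefore shows that the
algorithms are implemented correctly and behave as designed under their
own assumptions -- it does not certify performance on real microarray
data, where variance moderation (e.g. empirical-Bayes approaches) and
identifier curation matter.

Problem sizes used in the shipped validation: oracle agreement on 200
random graphs of up to 12 nodes for the centralities and 100 for the
clique enumeration; recovery on 20 replicates of a 1000-gene screen
with 50 planted DEGs and 20 replicates of an 8-clique planted in a
50-node background. These sizes make every brute-force oracle exact and
the whole suite quick to run.

## Known limitations

* Plain t-tests, not moderated ones: with very few samples per group
  the per-gene variance estimates are noisy, and an empirical-Bayes
  approach would be more powerful. The pipeline accepts any thresholds,
  so results from other screening tools can be fed in at the
  `integrate_degs()` stage instead.
* Exact symbol matching; no alias or identifier mapping.
* The mined modules depend on `theta` and the hub count; there is no
  universally right setting, and the defaults are starting points, not
  recommendations for every network.
* Edge weights never influence clique enumeration, MCC or cliqueness --
  density is purely topological throughout the module-mining stage.
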