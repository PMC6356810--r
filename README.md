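# ncmnet

Characteristic-gene identification from interaction-network topology,
for researchers who have two-group (e.g. tumor vs. normal) expression
data and want to go beyond a flat list of differentially expressed
genes. The pipeline: screen DEGs per dataset, merge them across
datasets, place them in a weighted interaction network, rank every gene
by network topology, mine the network's high-density modules, and test
gene lists for gene-set over-representation — all offline and fully
seeded.

## The measures at the core

For a node *v* in a component of *n* nodes, the package computes degree
centrality DC(v) = deg(v)/(n−1), unnormalized betweenness
BC(v) = Σ σ<sub>ivj</sub>/σ<sub>ij</sub>, closeness in its farness form
CC(v) = mean shortest-path distance (smaller = more central), the local
clustering coefficient CLC(v) = 2e/(k(k−1)), eccentricity centrality
EC(v) = 1/max distance, and the composite **Normalized Centrality
Measure**

> NCM(v) = (BC(v)/BC<sub>max</sub> + DC(v)/DC<sub>max</sub>) / (CC(v)/CC<sub>max</sub>)

which is large for genes that are simultaneously local hubs, global
brokers, and close to the rest of the network. Module mining scores hub
candidates by **Maximal Clique Centrality**, MCC(v) = Σ (|C|−1)! over
the maximal cliques C containing *v*, and grows modules from each hub's
largest clique under a density ("cliqueness") threshold,
cliqueness(G) = E(G)/C(|V(G)|, 2). DEG screening uses pooled-variance
t-tests with Benjamini–Hochberg adjustment (up: adjusted p < 0.05 and
logFC > 2; down: logFC < −2); enrichment is a one-sided hypergeometric
upper tail over GMT gene sets.

## Worked example

Simulate a 500-gene two-group study with 25 planted 3-log2-unit shifts
and a 60-node network with two planted dense modules, then run the whole
chain:

```r
library(ncmnet)

sim <- simulate_expression(expression_sim_spec(
  n_genes = 500, n_de = 25, true_lfc = 3, noise_sd = 1,
  n_per_group = 10, seed = 42))
degs <- deg_screen(sim$dataset)
degs
#> <deg_table> 500 genes from sim42
#>   thresholds: p_adj < 0.05, |logFC| > 2
#>   up: 25   down: 0   ns: 475

net_sim <- simulate_network(network_sim_spec(
  n_nodes = 60, p_background = 0.06,
  planted_modules = list(c(7, 1.0), c(5, 0.95)), seed = 42))
net <- net_sim$network
net
#> <gene_network> 60 nodes, 151 edges, 1 component(s)

ct <- centrality_table(net)
rank_nodes(ct, "NCM", 5)
#> [1] "N02" "N23" "N44" "N01" "N37"

mods <- mine_dense_modules(net, n_hubs = 10, theta = 0.8)
mods[[1]]
#> <dense_module> 7 nodes, 21 edges, cliqueness 1 (seed hub N02)
#>   N01, N02, N03, N04, N05, N06, N07
```

The screen calls exactly the 25 planted genes (all `up`, nothing else),
the top NCM gene `N02` belongs to the larger planted module, and the
mined modules recover both planted blocks exactly — `mods[[1]]` is the
planted 7-clique (nodes N01–N07), with cliqueness 1. Testing the first
module against the planted membership as a gene-set collection gives a
hypergeometric p of 2.6e-09 for the true set and 1.0 for the background
set.

A command-line interface covering every step
(`degs`, `integrate`, `build-net`, `rank`, `modules`, `enrich`,
`simulate`) is installed at
`system.file("cli", "ncmnet.R", package = "ncmnet")`; run it with
`Rscript ncmnet.R <subcommand> --help`-style arguments as shown in
`?cli_main`.

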