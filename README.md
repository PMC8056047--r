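# krnet — key-regulator discovery in disease interaction networks

`krnet` implements a graph-theoretical pipeline for finding the *key
regulators* (KRs) of a disease protein–protein interaction (PPI) network.
The intended user starts from a manually curated list of disease-associated
*seed genes* and a confidence-scored interaction list (the STRING export
dialect, filtered at combined score > 0.50), and wants to know which seed
genes — together with their direct interaction partners — sit so deep in
the network's community structure that they plausibly organize it.

## The method

**Topology.** Six per-node properties are computed and aggregated by degree
*k*: the degree distribution *P(k) = n_k/N*, local clustering *C(k)*,
neighborhood connectivity *C_N(k)*, betweenness *C_B(k)*, closeness
*C_C(k)* and eigenvector centrality *C_E(k)*. Each is fitted with the
two-parameter power law *TP ∼ a₀·k^a₁*; the sign pattern of the six
exponents classifies the network (negative degree-distribution and
clustering exponents with positive centrality exponents read as a weakly
hierarchical, scale-free, assortative architecture). A Clauset-style
semiparametric bootstrap (default 2,500 resamples) tests whether the degree
sequence is compatible with a discrete power law.

**Hierarchy.** The network is decomposed recursively with Newman's
leading-eigenvector (LEV) method: each community is split along the leading
eigenvector of its modularity matrix

> Q = (1/2m) Σᵢⱼ (Aᵢⱼ − kᵢkⱼ/2m) δ(Cᵢ, Cⱼ)

as long as the split increases Q, and the recursion descends until the
*motif level*: a community qualifies only if it contains at least one
triangle G(3,3), and a community that is a single triangle, or that no
longer splits, is terminal.

**Key regulators.** Seed genes are traced from the root down the community
tree. A seed that reaches a terminal community *inside a triangle* is a
key regulator, and the other members of its terminal triangles are its
partner KRs. Each KR's per-level regulatory share is
*P_KR = x⁽ˡ⁾/E⁽ˡ⁾* — its in-community edge count over the community's edge
count — and its network-wide popularity is its competition rank by degree.

**Cohesion and robustness.** Each community's Constant Potts Model
Hamiltonian energy *H = γn² − e* (γ = 0.5) and the local-community-paradigm
correlation (Pearson correlation of common-neighbour counts CN vs
local-community links LCL over edges with CN > 1) quantify per-level
cohesion. Rich-club organization is scored by φ(k) = 2E₍₎ₖ/(N₍₎ₖ(N₍₎ₖ−1))
normalized against degree-preserving rewired nulls, extracting nodes where
φ_norm ≥ 1.1. Finally, in-silico knockout of each KR motif at every level
of its path recomputes the six exponents and the energy, measuring the
motif's structural load.

Synthetic generators (preferential attachment, hierarchical clique
replication, planted-KR modular networks, planted rich clubs,
Erdős–Rényi controls) make every stage testable without any external data.
The curated 117-gene seed table ships with the package
(`fixture_gene_table()`).

## Worked example

```r
library(krnet)

gen  <- gen_planted_kr(n_communities = 4, subs_per_community = 2,
                       n_seeds = 3, seed = 42)
tree <- decompose_network(gen$network)
tree
#> Community tree: 13 communities over levels 0..2 (8 terminal, 0 pruned) on 32 nodes / 52 edges

report <- identify_key_regulators(tree, trace_seeds(tree, gen$seed_genes))
report
#> Key-regulator report: 3 seed KR(s) [g1_1_1, g1_2_1, g4_2_1], 6 partner KR(s)
#>   [g1_1_2, g1_1_3, g1_2_2, g1_2_3, g4_2_2, g4_2_3], 3 motif(s)

level_summary(tree)
#> # A tibble: 3 × 5
#>   level n_communities mean_q total_he mean_lcp_corr
#>   <int>         <int>  <dbl>    <dbl>         <dbl>
#> 1     0             1  0.673      460            NA
#> 2     1             4  0.333       80            NA
#> 3     2             8 NA           24            NA

kr_probability(tree, report$seed_krs[1])
#> # A tibble: 3 × 6
#>   gene   level community     x     e   p_kr
#>   <chr>  <int> <chr>     <int> <dbl>  <dbl>
#> 1 g1_1_1     0 c0            2    52 0.0385
#> 2 g1_1_1     1 c0.1          2    12 0.167
#> 3 g1_1_1     2 c0.1.1        2     5 0.4

knockout_experiment(tree, report$motifs$members[[1]])
#> Knockout of motif {g1_1_1, g1_1_2, g1_1_3} across 3 level(s):
#>   level 0 (c0): HE 460.00 -> 374.50
#>   level 1 (c0.1): HE 20.00 -> 6.50
#>   level 2 (c0.1.1): HE 3.00 -> 0.50
```

Reading the output: the three planted seed genes are recovered as seed KRs
with exactly their two triangle partners each; the regulatory share of
`g1_1_1` rises from 3.9% of the root network's edges to 40% of its
terminal community's edges (KRs act "at the grassroots"), and removing its
motif strictly lowers the Hamiltonian energy at every level — the wiring
cost the motif was carrying.

Real data flows through the same verbs:

```r
edges <- read_scored_edges("string_edges.tsv", threshold = 0.5)
g     <- build_network(edges)
seeds <- read_gene_table("seed_genes.tsv")   # or fixture_gene_table()
cfg   <- pipeline_config(edges_path = "string_edges.tsv",
                         genes_path = "seed_genes.tsv",
                         seed = 1, out_dir = "reports")
res   <- run_full_pipeline(cfg)              # writes JSON + TSV reports
```

`tidy()`/`glance()` methods flatten fitted objects, and
`autoplot()`/`plot_degree_profile()` draw the standard diagnostic figures.

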