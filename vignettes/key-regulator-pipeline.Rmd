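---
title: "Identifying key regulators of a disease interaction network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying key regulators of a disease interaction network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(krnet)
```

## The problem

Complex diseases rarely trace back to a single gene. The working model in
network medicine is that disease phenotypes emerge from perturbations of a
protein–protein interaction (PPI) network, and that the genes which matter
most are not necessarily the hubs but the ones embedded in the network's
deep modular structure. `krnet` operationalizes one such analysis: starting
from a curated set of disease-associated *seed genes* and a
confidence-scored interaction list, it characterizes the network's
architecture, decomposes it into a hierarchy of communities, and declares
as *key regulators* (KRs) the seed genes that persist to the deepest level
of that hierarchy inside a triangle motif, together with the triangle's
other members.

This vignette records the model, its assumptions, the parameter defaults,
the numerical conventions, and the limits of what the packaged synthetic
fixtures demonstrate.

## Network assembly

Interactions arrive as `node_a node_b score` rows. Two conventions are
fixed here:

* **Score scale.** STRING exports use either a unit scale or a 0–1000
  scale. If any score exceeds 1 the whole file is treated as
  thousand-scale and divided by 1000. The retention rule is *strictly*
  greater than the threshold (default 0.50), so a score of exactly 0.5 is
  excluded.
* **Simple undirected graph.** Symmetric duplicates collapse to one edge
  keeping the maximum score (scores are confidences, not weights to sum);
  self-loops are dropped with a warning. One gene maps to one protein
  node. Gene symbols preserve case but are matched case-insensitively.

## Topological characterization

Six per-node properties are computed: degree, local clustering,
neighborhood connectivity (mean neighbor degree), betweenness, closeness
and eigenvector centrality. Conventions for degenerate cases:

* clustering is undefined (missing) below degree 2;
* betweenness is the raw sum over unordered pairs; a flag rescales by
  \((N-1)(N-2)/2\) for compatibility with GUI tools. Only the fitted
  exponent matters downstream and a global rescaling is absorbed by the
  prefactor;
* closeness of a node uses only the nodes of its connected component —
  \((N_c-1)/\sum_j d_{ij}\) — so disconnected graphs (a routine outcome of
  knockouts) remain well defined;
* eigenvector centrality is the Perron vector of the largest connected
  component, unit Euclidean norm, non-negative; nodes outside that
  component are missing. The principal eigenvector is component-local, so
  reporting values across components would be arbitrary;
* shortest paths are unweighted: interaction scores are confidence values,
  not distances.

Properties are aggregated by degree (one row per observed \(k\), means
over nodes of that degree), and each property is fitted with
\(y = a_0 k^{a_1}\).

### Power-law fitting conventions

The default fit is linear least squares of \(\log y\) on \(\log k\)
(stable, exactly scale-equivariant; `method = "direct"` refines by
nonlinear least squares on the original scale). The fit uses the full
degree range — no lower-cutoff search — matching the full-range fits this
analysis style reports.

One genuinely open choice is whether to fit one point per observed degree
or to weight each degree by its node count \(n_k\). Both are available
(`points = "means"` / `"raw"`). For heavy-tailed degree sequences the
difference is material: on a preferential-attachment network of 2,000
nodes the unweighted fit is flattened by the long run of singleton
degrees in the tail (each contributing an identical \(P(k) = 1/N\)) and
lands near \(-2.15\), while the node-weighted fit lands near \(-2.3\) and
the maximum-likelihood discrete fit near \(-2.44\), both consistent with
the scale-free regime between \(-2.2\) and \(-3.6\) expected for this
generator. The package therefore uses degree-aggregated means for the
descriptive per-property exponent table (where relative signs, not exact
magnitudes, drive the classification) and the node-weighted or ML fit
wherever the degree-distribution exponent itself is the quantity of
interest — the tests and the acceptance script exercise the latter.

Goodness of fit for the degree distribution follows the semiparametric
bootstrap: fit a discrete power law by maximum likelihood with the lower
bound fixed at the sample minimum, measure the Kolmogorov–Smirnov distance
to the fitted law, then draw `n_resamples` synthetic samples from the
fitted law, refit each, and report the fraction whose KS distance exceeds
the observed one. The default 2,500 resamples mirrors standard practice;
tests use 200–500. Values above 0.1 are read as "power law plausible".
The classification of the six exponent signs — negative degree
distribution and clustering, positive neighborhood connectivity and
centralities — is labelled "weak hierarchical scale-free, assortative";
the neighborhood-connectivity sign alone decides
assortative/disassortative mixing.

## Hierarchical decomposition

Communities are found by Newman's leading-eigenvector method: recursive
spectral bisection along the leading eigenvector of the (generalized)
modularity matrix, accepting a bisection only when it increases
modularity. The implementation is deterministic by construction: the
dense symmetric eigensolver is used, the leading eigenvector's sign is
fixed so its largest-magnitude entry is positive, and exactly-zero
entries join the positive side. Disconnected components are separated
before bisection.

`decompose_network()` recurses: each community's induced subgraph (edges
to the outside ignored) is treated as a standalone network and split
again. Three rules end a branch:

* a community with no triangle is **pruned** — it is kept in the tree for
  audit but excluded from deeper levels and level summaries. The
  qualification criterion is applied immediately, without recursing into
  triangle-free fragments first;
* a community that is a single triangle, or whose best split no longer
  increases modularity, is **terminal**;
* a depth cap (`max_levels`, default 10) guards against pathological
  recursion; six levels is typical for a real PPI network of ~1,000
  nodes.

Every non-pruned leaf therefore contains at least one triangle.

## Key regulators

Each seed gene is traced root-to-leaf through the tree. A seed whose
trace ends in a terminal community *and* which belongs to a triangle of
that community is a seed-KR; the other two members of each such triangle
are partner KRs (a seed lying in two triangles sharing an edge
contributes the union — a four-member motif). Three statistics accompany
the report:

* **Regulatory share** \(P_{KR} = x^{(l)}/E^{(l)}\): the gene's
  in-community degree over the community's internal edge count, per level
  of its trace. Internal edges are used for both numerator and
  denominator, keeping the ratio a proportion of the community's own
  wiring. A community with no internal edges yields a missing value.
* **Popularity rank**: competition ("1224") ranking by descending degree
  over all network nodes — the convention matching ordinal ranks quoted
  in the field.
* **Dropped seeds**: seeds absent from the assembled network are listed,
  not raised as errors — curated genes routinely fail to enter the
  interaction network.

## Cohesion: energy and LCP

The Constant Potts Model energy of a community is \(H = \gamma n_c^2 -
e_c\) with resolution \(\gamma = 0.5\) (configurable); a level's energy is
the sum over its non-pruned communities. Fragmentation shrinks
\(\sum n_c^2\) faster than \(\sum e_c\), so energy declines down a
well-formed hierarchy, and a motif knockout that removes fewer incident
edges than \(\gamma(6n-9)\) strictly lowers it — both behaviours are
asserted on the planted fixtures.

The local-community-paradigm statistics are computed per edge:
\(CN\) common neighbours of the endpoints, \(LCL\) edges among those
common neighbours (bounded by \(CN(CN-1)/2\)). The LCP correlation is the
Pearson correlation of \((CN, LCL)\) over edges with \(CN > 1\) — the
restriction is applied literally as edge inclusion. Zero-variance cases
(every qualifying edge identical, e.g. a clique) are reported missing
rather than zero, and level averages exclude both missing and exactly-zero
correlations. LCP is computed on each community's induced subgraph,
without external context. Link prediction — the LCP theory's original
application — is out of scope; only the compactness diagnostic is
implemented.

## Rich-club analysis

\(\phi(k)\) is computed for every cut \(k\) from 0 to the maximum degree
minus one wherever at least two nodes exceed the cut (no truncation at
the third-highest degree — that is an artifact of particular networks,
and a truncation option would only hide rows). Normalization divides by
the *mean* \(\phi\) of `n_null` (default 100) degree-preserving rewired
networks, each produced by `n_swaps_factor * |E|` (default 10×) attempted
double-edge swaps with rejection of loops and multi-edges. Node
extraction takes the nodes whose degree has \(\phi_{norm} \ge 1.1\); the
default applies the rule literally per degree, and a contiguous-range
mode treats every degree above the smallest passing one as qualifying —
useful because the top one or two degrees of a small network often define
clubs of fewer than two nodes or zero edges, where per-degree values are
noise.

## Knockout experiments

A motif knockout removes the motif's *nodes* (with all incident edges) —
not merely its internal edges — consistent with degree changes a node
deletion produces. At every level of the motif's path the level's
community subgraph is reduced and the six exponents and the energy are
recomputed; post-knockout subgraphs with fewer than three usable degree
points report missing fits rather than forcing one, and fragmented
remnants are analyzed as-is with the component-aware conventions above.

## Synthetic data: what it shows and what it does not

The generators produce networks with the statistical features the
analysis assumes, each deterministic under its seed:

* `gen_scale_free()` — preferential attachment (degree exponent near −3
  in the large-\(n\) limit; the \(n = 2000, m = 2\) instances used in
  tests fit between −2.2 and −3.6);
* `gen_hierarchical()` — replicated cliques wired to a central hub, the
  construction whose clustering falls with degree;
* `gen_planted_kr()` — the end-to-end fixture. Sub-communities are
  four-node "diamonds" (a 4-clique minus one edge): dense enough that no
  modularity-positive split exists inside them, with a designated seed
  vertex lying in exactly one triangle. Two parallel bridges chain the
  diamonds within a community and a ring joins communities, always
  through non-seed vertices and never creating triangles. An earlier
  design that decorated each triangle with pendant vertices was rejected:
  splitting pendant pairs off has higher modularity than preserving the
  triangle, so the decomposition legitimately dissected the planted
  motifs. The diamond construction makes the planted truth the provable
  optimum at both hierarchy levels at the default sizes (4 communities ×
  2 sub-communities; the inter-module edge fraction is kept an order of
  magnitude below the intra-block density);
* `gen_planted_richclub()` — a 6-clique core over 60 sparse peripheral
  nodes (attachment probability 0.03): the core's mutual wiring exceeds
  what its degree sequence implies;
* `gen_erdos_renyi()` — the homogeneous control, whose normalized
  rich-club curve stays near 1.

Passing tests on these fixtures establishes that the machinery computes
the defined quantities correctly and recovers structure that is genuinely
present. It does not establish that a real PPI network has such
structure: real networks carry study bias (well-studied proteins have
more recorded interactions), false-positive edges below any threshold,
and community structure far from planted block models. The fixtures also
cannot validate any particular biological KR list — that depends entirely
on the input interaction snapshot.

## Problem sizes and reproducibility

Test and acceptance runs use 200 random graphs of up to 50 nodes for
oracle-equivalence checks, preferential-attachment networks of 2,000
nodes for exponent recovery, 500-resample bootstraps over five seeds for
the goodness-of-fit discrimination, and 100 rewired nulls over five seeds
for rich-club detection — sizes chosen so each property is measured with
comfortable margins while the whole suite completes in minutes. All
randomness flows from explicit integer seeds (the pipeline derives
per-stage seeds from one master seed by fixed offsets), and two pipeline
runs with the same configuration write byte-identical reports; the output
directory is deliberately excluded from the provenance echo for that
reason.

## Known limitations

* The leading-eigenvector method is a greedy bisection heuristic; it can
  return sub-optimal partitions (no Kernighan–Lin refinement is applied),
  and community detection on networks whose modularity landscape is flat
  is unstable under any method.
* The dense eigensolver makes decomposition O(n³) per split; it is
  comfortable to a few thousand nodes, which covers the intended use, but
  is not a large-graph tool.
* Exponent classification trusts signs, not magnitudes; near-zero
  exponents should be read with their \(r^2\).
* The bootstrap goodness of fit fixes the lower cutoff at the sample
  minimum (full-range fits); samples that are power-law only in the tail
  will be rejected.
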