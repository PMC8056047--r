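#' Scale-free network by preferential attachment
#'
#' Growth model in which each new vertex attaches to `m` existing vertices
#' with probability proportional to their degree, yielding a power-law
#' degree distribution (exponent near -3 in the large-n limit).
#'
#' @param n Number of nodes (> m).
#' @param m Edges added per new vertex (>= 1).
#' @param seed Integer seed.
#' @return An undirected `igraph` graph with `n` nodes, vertices named
#'   `v1..vn`; the generator call is recorded in graph attributes.
#' @export
gen_scale_free <- function(n, m, seed = 1L) {
  stopifnot(n > m, m >= 1)
  set.seed(seed)
  g <- igraph::sample_pa(n, m = m, directed = FALSE)
  igraph::V(g)$name <- paste0("v", seq_len(n))
  g <- igraph::set_graph_attr(g, "generator", "scale_free")
  igraph::set_graph_attr(g, "seed", as.integer(seed))
}

#' Hierarchical modular network (replicated-clique construction)
#'
#' Deterministic hierarchical model: a base clique of `motif_size` nodes is
#' replicated `motif_size - 1` times at each level and every peripheral
#' node of the replicas is wired to the central hub, producing a network
#' whose clustering coefficient decreases with degree — the hierarchical
#' signature — while every terminal module contains triangles.
#'
#' @param levels Number of construction levels (>= 1; `levels = 1` is the
#'   bare clique).
#' @param motif_size Clique size (>= 3, default 4).
#' @param seed Integer seed (recorded for provenance; the construction is
#'   deterministic).
#' @return An undirected `igraph` graph with `motif_size^levels` nodes.
#' @export
gen_hierarchical <- function(levels, motif_size = 4, seed = 1L) {
  stopifnot(levels >= 1, motif_size >= 3)
  m <- motif_size
  # edge list construction; node 1 is the global hub
  edges <- utils::combn(seq_len(m), 2)
  peripheral <- 2:m
  n_nodes <- m
  for (lev in seq_len(levels - 1)) {
    block <- n_nodes
    new_edges <- edges
    new_periph <- peripheral
    for (r in seq_len(m - 1)) {
      off <- r * block
      new_edges <- cbind(new_edges, edges + off)
      new_periph <- c(new_periph, peripheral + off)
    }
    replica_periph <- setdiff(new_periph, peripheral)
    new_edges <- cbind(new_edges, rbind(rep(1L, length(replica_periph)),
                                        replica_periph))
    edges <- new_edges
    peripheral <- new_periph
    n_nodes <- m * block
  }
  g <- igraph::make_graph(as.vector(edges), n = n_nodes, directed = FALSE)
  g <- igraph::simplify(g)
  igraph::V(g)$name <- paste0("h", seq_len(n_nodes))
  g <- igraph::set_graph_attr(g, "generator", "hierarchical")
  igraph::set_graph_attr(g, "seed", as.integer(seed))
}

#' Two-level modular network with planted key regulators
#'
#' Builds a network of `n_communities` communities, each made of
#' `subs_per_community` sub-communities. Every sub-community is a
#' four-node "diamond" (a 4-clique minus one edge): a dense block that
#' modularity-based splitting keeps intact, whose designated seed vertex
#' belongs to exactly one triangle. Sub-communities are chained within a
#' community by two parallel bridges, and communities are joined in a
#' ring, always through non-seed vertices and never creating new
#' triangles, so inter-module connectivity stays far below the intra-block
#' density. `n_seeds` seed genes are placed on distinct sub-communities
#' (chosen under `seed`); the true key regulators are those seeds plus,
#' for each, its two triangle partners.
#'
#' @param n_communities Number of top-level communities (default 4).
#' @param subs_per_community Sub-communities per community (default 2).
#' @param n_seeds Number of planted seed genes (default 3; at most the
#'   number of sub-communities).
#' @param seed Integer seed controlling seed placement.
#' @return A list with `network` (igraph), `seed_genes` (tibble with
#'   `symbol` and `gene_id`) and `truth` (tibble: `seed`, `partner_1`,
#'   `partner_2`, `sub_community`).
#' @export
gen_planted_kr <- function(n_communities = 4, subs_per_community = 2,
                           n_seeds = 3, seed = 1L) {
  stopifnot(n_communities >= 2, subs_per_community >= 1)
  n_subs <- n_communities * subs_per_community
  if (n_seeds > n_subs) stop("n_seeds must not exceed the number of terminal triangles")

  # diamond vertices: 1 = seed (one triangle: 1-2-3), 2/3 = partners,
  # 4 = opposite vertex (carries inter-module bridges with vertex 2)
  node <- function(ci, si, t) sprintf("g%d_%d_%d", ci, si, t)
  edges <- character(0)
  add_edge <- function(a, b) edges <<- c(edges, a, b)
  for (ci in seq_len(n_communities)) {
    for (si in seq_len(subs_per_community)) {
      v <- vapply(1:4, function(t) node(ci, si, t), character(1))
      add_edge(v[1], v[2]); add_edge(v[1], v[3]); add_edge(v[2], v[3])
      add_edge(v[2], v[4]); add_edge(v[3], v[4])
    }
    # chain sub-communities with paired bridges through vertices 2 and 4
    if (subs_per_community > 1) {
      for (si in seq_len(subs_per_community - 1)) {
        add_edge(node(ci, si, 2), node(ci, si + 1, 2))
        add_edge(node(ci, si, 4), node(ci, si + 1, 4))
      }
    }
  }
  # ring of communities through vertex 4 of the first sub-community
  for (ci in seq_len(n_communities)) {
    cj <- if (ci == n_communities) 1L else ci + 1L
    add_edge(node(ci, 1, 4), node(cj, 1, 4))
  }
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  g <- igraph::simplify(g)
  g <- igraph::set_graph_attr(g, "generator", "planted_kr")
  g <- igraph::set_graph_attr(g, "seed", as.integer(seed))

  set.seed(seed)
  subs <- expand.grid(ci = seq_len(n_communities),
                      si = seq_len(subs_per_community))
  picked <- subs[sample(nrow(subs), n_seeds), , drop = FALSE]
  truth <- if (n_seeds == 0) {
    tibble::tibble(seed = character(), partner_1 = character(),
                   partner_2 = character(), sub_community = character())
  } else {
    tibble::tibble(
      seed = mapply(node, picked$ci, picked$si, 1L),
      partner_1 = mapply(node, picked$ci, picked$si, 2L),
      partner_2 = mapply(node, picked$ci, picked$si, 3L),
      sub_community = sprintf("g%d_%d", picked$ci, picked$si)
    )
  }
  seed_genes <- tibble::tibble(symbol = truth$seed,
                               gene_id = seq_len(nrow(truth)))
  list(network = g, seed_genes = seed_genes, truth = truth)
}

#' Network with a planted rich club
#'
#' A clique core of `core` nodes plus `periphery` sparse peripheral nodes;
#' every non-core-core node pair is linked independently with probability
#' `p_periph`. The core's mutual connectivity far exceeds what its degree
#' sequence implies, so the normalized rich-club coefficient is elevated at
#' the core's degrees.
#'
#' @param core Clique size (>= 3, default 6).
#' @param periphery Number of peripheral nodes (default 60).
#' @param p_periph Attachment probability (default 0.03).
#' @param seed Integer seed.
#' @return An undirected `igraph` graph with `core + periphery` nodes.
#' @export
gen_planted_richclub <- function(core = 6, periphery = 60, p_periph = 0.03,
                                 seed = 1L) {
  stopifnot(core >= 3, periphery >= 0, p_periph >= 0, p_periph <= 1)
  n <- core + periphery
  set.seed(seed)
  edges <- utils::combn(seq_len(core), 2)
  if (periphery > 0 && p_periph > 0) {
    pairs <- utils::combn(seq_len(n), 2)
    noncore <- pairs[, pairs[2, ] > core, drop = FALSE]
    hit <- stats::runif(ncol(noncore)) < p_periph
    edges <- cbind(edges, noncore[, hit, drop = FALSE])
  }
  g <- igraph::make_graph(as.vector(edges), n = n, directed = FALSE)
  g <- igraph::simplify(g)
  igraph::V(g)$name <- c(paste0("core", seq_len(core)),
                         if (periphery > 0) paste0("p", seq_len(periphery)))
  g <- igraph::set_graph_attr(g, "generator", "planted_richclub")
  igraph::set_graph_attr(g, "seed", as.integer(seed))
}

#' Erdős–Rényi random graph
#'
#' Homogeneous random control network: every node pair is linked
#' independently with probability `p`. Carries no rich club, hierarchy or
#' scale-free structure.
#'
#' @param n Number of nodes.
#' @param p Edge probability.
#' @param seed Integer seed.
#' @return An undirected `igraph` graph.
#' @export
gen_erdos_renyi <- function(n, p, seed = 1L) {
  stopifnot(n >= 1, p >= 0, p <= 1)
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- paste0("v", seq_len(n))
  g <- igraph::set_graph_attr(g, "generator", "erdos_renyi")
  igraph::set_graph_attr(g, "seed", as.integer(seed))
}

#' Packaged curated seed-gene table
#'
#' The curated table of 117 human genes reported as risk factors for spina
#' bifida, shipped with the package (symbol, numeric gene ID, description,
#' cytogenetic location, citation tag).
#'
#' @return A tibble with 117 rows, as from [read_gene_table()].
#' @export
fixture_gene_table <- function() {
  read_gene_table(system.file("extdata", "sb_seed_genes.tsv",
                              package = "krnet", mustWork = TRUE))
}
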