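#' Constant Potts Model Hamiltonian energy of a community
#'
#' The per-community energy term \eqn{\gamma n_c^2 - e_c}, where \eqn{n_c}
#' and \eqn{e_c} are the community's node and internal-edge counts and
#' \eqn{\gamma} is the resolution parameter acting as an edge-density
#' threshold (default 0.5). The energy is additive over disjoint
#' communities.
#'
#' @param community An `igraph` graph (a community's induced subgraph) or
#'   edge data frame.
#' @param gamma Resolution parameter (default 0.5).
#' @return A list with `n_c`, `e_c`, `gamma` and `he`.
#' @export
hamiltonian_energy <- function(community, gamma = 0.5) {
  g <- as_kr_graph(community)
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  list(n_c = n, e_c = e, gamma = gamma, he = gamma * n^2 - e)
}

#' Total Hamiltonian energy of one hierarchy level
#'
#' Sums the Constant Potts Model energy over all non-pruned communities at
#' the given level of a community tree.
#'
#' @param tree A `community_tree`.
#' @param level Level index (0 = full network).
#' @param gamma Resolution parameter (default 0.5).
#' @return The summed energy (a single number).
#' @export
level_hamiltonian <- function(tree, level, gamma = 0.5) {
  stopifnot(inherits(tree, "community_tree"))
  recs <- Filter(function(r) !r$pruned && r$level == level, tree$index)
  if (length(recs) == 0) stop("no non-pruned communities at level ", level)
  sum(vapply(recs, function(r) gamma * r$n_c^2 - r$e_c, numeric(1)))
}

#' Local-community-paradigm statistics of a network
#'
#' For every edge \eqn{\{x, y\}} computes the common-neighbor count
#' \eqn{CN = |S(x) \cap S(y)|} (endpoints excluded) and the
#' local-community-link count \eqn{LCL}, the number of edges among those
#' common neighbors (bounded above by \eqn{CN(CN-1)/2}). The LCP
#' correlation is the Pearson correlation between CN and LCL over the edges
#' with CN > 1; it is reported missing when fewer than two edges qualify or
#' when either variable is degenerate (zero variance).
#'
#' @param network An `igraph` graph or edge data frame with at least one
#'   edge.
#' @return A list of class `lcp_stats` with `edges` (tibble `node_a`,
#'   `node_b`, `cn`, `lcl`) and `lcp_corr` (real in \[-1, 1\] or `NA`).
#' @export
lcp_stats <- function(network) {
  g <- as_kr_graph(network)
  m <- igraph::ecount(g)
  if (m == 0) stop("lcp_stats needs a network with at least one edge")
  nbrs <- igraph::adjacent_vertices(g, igraph::V(g))
  nbrs <- lapply(nbrs, as.integer)
  el <- igraph::as_edgelist(g, names = FALSE)
  cn <- integer(m)
  lcl <- integer(m)
  for (i in seq_len(m)) {
    common <- intersect(nbrs[[el[i, 1]]], nbrs[[el[i, 2]]])
    cn[i] <- length(common)
    lcl[i] <- if (cn[i] >= 2) {
      igraph::ecount(igraph::induced_subgraph(g, common))
    } else 0L
  }
  names_el <- igraph::as_edgelist(g, names = TRUE)
  edges <- tibble::tibble(node_a = names_el[, 1], node_b = names_el[, 2],
                          cn = cn, lcl = as.integer(lcl))
  qual <- edges$cn > 1
  lcp_corr <- if (sum(qual) < 2 ||
                  stats::sd(edges$cn[qual]) == 0 ||
                  stats::sd(edges$lcl[qual]) == 0) {
    NA_real_
  } else {
    stats::cor(edges$cn[qual], edges$lcl[qual])
  }
  structure(list(edges = edges, lcp_corr = lcp_corr), class = "lcp_stats")
}

#' @export
print.lcp_stats <- function(x, ...) {
  cat(sprintf("LCP statistics over %d edges (%d with CN > 1): LCP-corr = %s\n",
              nrow(x$edges), sum(x$edges$cn > 1),
              ifelse(is.na(x$lcp_corr), "NA", sprintf("%.3f", x$lcp_corr))))
  invisible(x)
}

#' Average LCP correlation of one hierarchy level
#'
#' Mean of the per-community LCP correlations over the non-pruned
#' communities at the given level, excluding communities whose correlation
#' is missing or exactly zero.
#'
#' @param tree A `community_tree`.
#' @param level Level index.
#' @return The average correlation, or `NA` when every community at the
#'   level is excluded.
#' @export
level_average_lcp <- function(tree, level) {
  stopifnot(inherits(tree, "community_tree"))
  recs <- Filter(function(r) !r$pruned && r$level == level, tree$index)
  if (length(recs) == 0) stop("no non-pruned communities at level ", level)
  vals <- vapply(recs, function(r) {
    if (r$e_c == 0) return(NA_real_)
    lcp_stats(community_subgraph(tree, r$id))$lcp_corr
  }, numeric(1))
  vals <- vals[!is.na(vals) & vals != 0]
  if (length(vals) == 0) NA_real_ else mean(vals)
}
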